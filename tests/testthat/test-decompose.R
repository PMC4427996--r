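test_that("surrogate column scores equal pairwise identity times coverage", {
  aln <- AaAlignment(c(a = "AAAX", b = "ACA-", c = "-CA-", d = "-CAA"))
  sc <- siteScores(surrogateColumnScores(aln))
  # col 1: residues A,A; identity 1; coverage 2/4
  expect_equal(unname(sc[1L]), 0.5)
  # col 2: A,C,C,C -> identity (0+3)/6 = 0.5, coverage 1
  expect_equal(unname(sc[2L]), 0.5)
  # col 3: all A -> 1.0
  expect_equal(unname(sc[3L]), 1.0)
  # col 4: X counts as coverage but not identity; residues A only -> <2 pairs
  expect_equal(unname(sc[4L]), 0)

  two <- AaAlignment(c(a = "A", b = "C"))
  expect_equal(unname(siteScores(surrogateColumnScores(two))), 0)
  expect_error(surrogateColumnScores(aln, c("a", "nope")), "nope")
  expect_true(all(siteScores(surrogateColumnScores(randomAlignment(8, 40))) >= 0))
})

test_that("score thresholding keeps exactly the columns at or above the cutoff", {
  st <- new("SiteScoreTable", columns = 1:3, scores = c(0.9, 0.3, 0.5),
            source = "external", imputed = integer())
  expect_identical(maskColumns(maskFromScores(st, 0.5)), c(1L, 3L))
  expect_identical(maskColumns(maskFromScores(st, 0)), 1:3)
  expect_warning(m <- maskFromScores(st, 1), "empty")
  expect_identical(length(maskColumns(m)), 0L)
})

test_that("exclusive partition removes shared and earlier-clade columns in order", {
  plan <- exclusivePartition(siteMask(c(1, 2), "shared"),
                             list(A = c(2, 3), B = c(3, 4)),
                             list(A = "a1", B = "b1"))
  expect_identical(maskColumns(plan@shared), c(1L, 2L))
  expect_identical(maskColumns(plan@cladeSpecific$A), 3L)
  expect_identical(maskColumns(plan@cladeSpecific$B), 4L)
  expect_identical(plan@removed, list(A = 2L, B = 3L))

  # shared empty and disjoint clade masks pass through unchanged
  p2 <- exclusivePartition(siteMask(integer(), "shared"),
                           list(A = c(1, 2), B = c(5, 6)),
                           list(A = "a1", B = "b1"))
  expect_identical(maskColumns(p2@cladeSpecific$A), c(1L, 2L))
  expect_identical(maskColumns(p2@cladeSpecific$B), c(5L, 6L))

  # shared covering everything empties every clade mask
  p3 <- exclusivePartition(siteMask(1:6, "shared"),
                           list(A = c(1, 3), B = c(2, 6)),
                           list(A = "a1", B = "b1"))
  expect_identical(length(maskColumns(p3@cladeSpecific$A)), 0L)
  expect_identical(length(maskColumns(p3@cladeSpecific$B)), 0L)

  expect_error(exclusivePartition(siteMask(1), list(A = 2, B = 3),
                                  list(A = c("t1"), B = c("t1"))),
               "overlapping")
})

test_that("decomposition concatenates shared then clade blocks with full provenance", {
  aln <- randomAlignment(6, 12, gapProb = 0)
  grouping <- fourGroupGrouping(taxonIds(aln)[1:2], taxonIds(aln)[3],
                                taxonIds(aln)[4:5], taxonIds(aln)[6])
  plan <- exclusivePartition(siteMask(c(2, 9), "shared"),
                             list(A = c(1, 9, 11), B = c(4, 11)),
                             list(A = taxonIds(aln)[1:3], B = taxonIds(aln)[4:6]))
  dec <- decomposeAlignment(aln, plan)
  expect_identical(dec@provenance$original_column, c(2L, 9L, 1L, 11L, 4L))
  expect_identical(dec@provenance$partition, c("shared", "shared", "A", "A", "B"))
  expect_identical(alignmentMatrix(dec@alignment),
                   alignmentMatrix(aln)[, c(2, 9, 1, 11, 4)])

  # gap-nonfocal blanks exactly the non-members at clade-specific columns
  gnf <- decomposeAlignment(aln, plan, mode = "gap-nonfocal")
  m <- alignmentMatrix(gnf@alignment)
  expect_true(all(m[4:6, 3:4] == "-"))  # B taxa at A-specific columns
  expect_true(all(m[1:3, 5] == "-"))    # A taxa at the B-specific column
  expect_identical(m[, 1:2], alignmentMatrix(aln)[, c(2, 9)])  # shared untouched

  expect_error(decomposeAlignment(aln, exclusivePartition(
    siteMask(99), list(A = 1, B = 2),
    list(A = taxonIds(aln)[1:3], B = taxonIds(aln)[4:6]))), "width")
})

test_that("informative-site counts add shared and clade-specific sizes", {
  plan <- exclusivePartition(siteMask(1:5, "shared"),
                             list(A = 6:8, B = integer()),
                             list(A = "a1", B = "b1"))
  expect_identical(informativeSites(plan, "A"), 8L)
  expect_identical(informativeSites(plan, "B"), 5L)
  expect_error(informativeSites(plan, "C"), "unknown clade")
})

test_that("random decompositions match brute-force set arithmetic", {
  withr::local_seed(99)
  for (i in 1:25) {
    nc <- sample(5:50, 1L)
    aln <- randomAlignment(5, nc)
    sharedRaw <- sort(sample(nc, sample(0:nc, 1L)))
    rawA <- sort(sample(nc, sample(0:nc, 1L)))
    rawB <- sort(sample(nc, sample(0:nc, 1L)))
    # independent oracle: plain set arithmetic
    expA <- setdiff(rawA, sharedRaw)
    expB <- setdiff(setdiff(rawB, sharedRaw), expA)
    total <- length(sharedRaw) + length(expA) + length(expB)
    if (total == 0L) next
    plan <- exclusivePartition(siteMask(sharedRaw, "shared"),
                               list(A = rawA, B = rawB),
                               list(A = taxonIds(aln)[1:2], B = taxonIds(aln)[3:4]))
    dec <- decomposeAlignment(aln, plan)
    expect_identical(nColumns(dec@alignment), total)
    expect_identical(sort(dec@provenance$original_column),
                     as.integer(sort(c(sharedRaw, expA, expB))))
    expect_false(anyDuplicated(dec@provenance$original_column) > 0)
    # retain mode conserves every column's residue multiset
    for (k in sample(nrow(dec@provenance), min(3L, nrow(dec@provenance)))) {
      expect_identical(sort(alignmentMatrix(dec@alignment)[, dec@provenance$new_column[k]]),
                       sort(alignmentMatrix(aln)[, dec@provenance$original_column[k]]))
    }
    # determinism: identical inputs, byte-identical output
    dec2 <- decomposeAlignment(aln, plan)
    expect_identical(alignmentMatrix(dec2@alignment), alignmentMatrix(dec@alignment))
  }
})
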