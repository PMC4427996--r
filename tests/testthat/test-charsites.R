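test_that("group profiles count, merge similar residues, and format like the reports", {
  # 65 G + 35 A in 100 taxa -> dominant G(65)
  aln1 <- AaAlignment(matrix(c(rep("G", 65), rep("A", 35)), ncol = 1,
                             dimnames = list(sprintf("t%03d", 1:100), NULL)))
  p <- groupResidueProfile(aln1, 1, taxonIds(aln1))
  expect_identical(formatProfile(p), "G(65)")
  expect_identical(p@dominantClass, "G")

  # 43 R + 37 K merge into R/K(80); A stays a singleton
  aln2 <- AaAlignment(matrix(c(rep("R", 43), rep("K", 37), rep("A", 20)),
                             ncol = 1, dimnames = list(sprintf("t%03d", 1:100), NULL)))
  p2 <- groupResidueProfile(aln2, 1, taxonIds(aln2))
  expect_identical(formatProfile(p2), "R/K(80)")
  expect_identical(sort(p2@classResidues[["R/K"]]), c("K", "R"))

  # merging is opportunistic: a lone K does not become a K/R class
  aln3 <- AaAlignment(matrix(c(rep("K", 60), rep("A", 40)), ncol = 1,
                             dimnames = list(sprintf("t%02d", 1:100), NULL)))
  expect_identical(formatProfile(groupResidueProfile(aln3, 1, taxonIds(aln3))),
                   "K(60)")

  # all gaps -> ineligible, undefined dominant
  aln4 <- AaAlignment(matrix("-", nrow = 4, ncol = 1,
                             dimnames = list(letters[1:4], NULL)))
  p4 <- groupResidueProfile(aln4, 1, letters[1:4])
  expect_false(p4@eligible)
  expect_identical(formatProfile(p4), "-")

  expect_error(groupResidueProfile(aln1, 1, character()), "empty")
  expect_error(groupResidueProfile(aln1, 5, taxonIds(aln1)), "range")

  # percentages displayed over non-gap non-X residues, rounded half-up
  aln5 <- AaAlignment(matrix(c(rep("G", 2), "A", rep("-", 3)), ncol = 1,
                             dimnames = list(letters[1:6], NULL)))
  p5 <- groupResidueProfile(aln5, 1, letters[1:6])
  expect_identical(formatProfile(p5), "G(67)")
  expect_true(p5@eligible)   # coverage exactly 1/2 still qualifies
  p6 <- groupResidueProfile(aln5, 1, letters[1:6], minNonGapFraction = 0.6)
  expect_false(p6@eligible)
})

test_that("radicality separates physiochemical super-categories", {
  expect_identical(radicality("G", "P"), "radical")
  expect_identical(radicality("D", "E"), "conservative")
  expect_identical(radicality("L", "M"), "conservative")
  expect_identical(radicality("R/K", "G"), "radical")
  expect_identical(radicality("F", "L/M"), "radical")       # aromatic vs aliphatic
  expect_identical(radicality(c("K", "R"), "H"), "conservative")
  expect_error(radicality("B", "A"), "unknown residue")
})

test_that("evaluateSite applies the relaxed definition with absolute sister absence", {
  # rare-A ingroup shares P with the pooled outgroup; sister is all G
  tc <- columnAlignment(commonA = rep("G", 4), rareA = rep("P", 4),
                        commonB = rep("P", 4), rareB = rep("P", 4))
  call <- evaluateSite(tc$alignment, 1, tc$grouping, ingroup = "A:rare")
  expect_identical(call@classification, "symplesiomorphy")
  expect_identical(call@definingClass, "P")
  expect_false(call@weak)
  expect_identical(call@radicality, "radical")

  # a single sister carrier vetoes the call regardless of group size
  tv <- columnAlignment(commonA = c(rep("G", 9), "P"), rareA = rep("P", 10),
                        commonB = rep("P", 10), rareB = rep("P", 10))
  expect_identical(evaluateSite(tv$alignment, 1, tv$grouping,
                                ingroup = "A:rare")@classification, "none")

  # uniform column: no absence possible anywhere
  tu <- columnAlignment(rep("A", 3), rep("A", 3), rep("A", 3), rep("A", 3))
  for (ing in c("A:rare", "A:common", "B:rare", "B:common"))
    expect_identical(evaluateSite(tu$alignment, 1, tu$grouping,
                                  ingroup = ing)@classification, "none")

  # synapomorphy: defining residue confined to the ingroup
  ts <- columnAlignment(commonA = rep("G", 4), rareA = rep("W", 4),
                        commonB = rep("G", 4), rareB = rep("G", 4))
  expect_identical(evaluateSite(ts$alignment, 1, ts$grouping,
                                ingroup = "A:rare")@classification, "synapomorphy")

  # ineligible ingroup (too many gaps) -> none with a reason code
  tg <- columnAlignment(commonA = rep("G", 4), rareA = c("P", "-", "-", "-"),
                        commonB = rep("P", 4), rareB = rep("P", 4))
  gcall <- evaluateSite(tg$alignment, 1, tg$grouping, ingroup = "A:rare")
  expect_identical(gcall@classification, "none")
  expect_identical(gcall@reason, "ineligible_ingroup")
})

test_that("weak symplesiomorphies are flagged and kept out of headline counts", {
  # ingroup all D, sister all G, outgroup 40% D (plurality, below threshold)
  tw <- columnAlignment(commonA = rep("G", 10), rareA = rep("D", 10),
                        commonB = c(rep("D", 5), rep("A", 3), rep("S", 2)),
                        rareB = c(rep("A", 3), rep("S", 3), rep("D", 3), "T"))
  call <- evaluateSite(tw$alignment, 1, tw$grouping, ingroup = "A:rare")
  expect_identical(call@classification, "symplesiomorphy")
  expect_true(call@weak)

  scan <- scanCharSites(tw$alignment, tw$grouping, ingroups = "A:rare")
  expect_identical(scan$counts$symplesiomorphies, 0L)
  expect_identical(scan$counts$weak, 1L)
})

test_that("outgroup pooling is taxon-weighted, with a per-form-majority alternative", {
  # V clears 50% only when both outgroup forms are pooled: 86% + 17% of 100+100
  tc <- columnAlignment(commonA = c(rep("V", 71), rep("A", 29)),
                        rareA = c(rep("E", 44), rep("K", 22), rep("L", 17), rep("I", 17)),
                        commonB = c(rep("V", 86), rep("A", 14)),
                        rareB = c(rep("E", 83), rep("V", 17)))
  pooled <- evaluateSite(tc$alignment, 1, tc$grouping, ingroup = "A:common")
  expect_identical(pooled@classification, "symplesiomorphy")
  expect_identical(pooled@definingClass, "V")
  expect_equal(pooled@outgroupShare, 103 / 200)

  perForm <- evaluateSite(tc$alignment, 1, tc$grouping, ingroup = "A:common",
                          params = charSiteParams(outgroupPooling = "per-form-majority"))
  # equal form sizes: the first maximal form (common B, 86% V) decides
  expect_identical(perForm@classification, "symplesiomorphy")
})

test_that("classifications are invariant to taxon and column permutations", {
  withr::local_seed(7)
  fx <- makeCharSiteBenchmark()
  aln <- fx$alignment
  scan <- scanCharSites(aln, fx$grouping)

  perm <- sample(nTaxa(aln))
  colperm <- sample(nColumns(aln))
  m <- alignmentMatrix(aln)[perm, colperm]
  scan2 <- scanCharSites(AaAlignment(m), fx$grouping)
  # relabel scan2's columns back to the original coordinates
  back <- scan2$calls
  back$column <- colperm[back$column]
  back <- back[order(back$column, back$ingroup), ]
  rownames(back) <- NULL
  expect_identical(back[, c("column", "ingroup", "classification", "defining_class")],
                   scan$calls[, c("column", "ingroup", "classification", "defining_class")])
})

test_that("swapping family labels mirrors ingroup and outgroup roles", {
  tc <- columnAlignment(commonA = rep("G", 4), rareA = rep("P", 4),
                        commonB = rep("P", 4), rareB = rep("P", 4))
  swapped <- taxonGrouping(tc$grouping@assignments$taxon,
                           ifelse(tc$grouping@assignments$family == "A", "B", "A"),
                           tc$grouping@assignments$form)
  orig <- evaluateSite(tc$alignment, 1, tc$grouping, ingroup = "A:rare")
  mirr <- evaluateSite(tc$alignment, 1, swapped, ingroup = "B:rare")
  expect_identical(orig@classification, mirr@classification)
  expect_identical(orig@definingClass, mirr@definingClass)
})

test_that("raising the share threshold never enlarges the call set", {
  fx <- makeCharSiteBenchmark()
  loose <- scanCharSites(fx$alignment, fx$grouping,
                         params = charSiteParams(shareThreshold = 0.5))
  strict <- scanCharSites(fx$alignment, fx$grouping,
                          params = charSiteParams(shareThreshold = 0.8))
  keyOf <- function(calls) paste(calls$column, calls$ingroup, calls$classification)
  expect_true(all(keyOf(strict$calls) %in% keyOf(loose$calls)))
  expect_lt(nrow(strict$calls), nrow(loose$calls))
})

test_that("random mixed-residue columns agree with the brute-force enumerator", {
  withr::local_seed(2024)
  ids <- list(commonA = sprintf("cA%d", 1:4), rareA = sprintf("rA%d", 1:4),
              commonB = sprintf("cB%d", 1:4), rareB = sprintf("rB%d", 1:4))
  grouping <- fourGroupGrouping(ids$commonA, ids$rareA, ids$commonB, ids$rareB)
  taxa <- unlist(ids, use.names = FALSE)
  # A, G, P are in no similarity class; the enumerator knows no classes
  alphabet <- c("A", "G", "P", "-")
  for (i in 1:300) {
    col <- sample(alphabet, 16, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    names(col) <- taxa
    aln <- AaAlignment(matrix(col, ncol = 1, dimnames = list(taxa, NULL)))
    for (ing in c("A:rare", "B:common")) {
      fam <- sub(":.*", "", ing)
      form <- sub(".*:", "", ing)
      other <- setdiff(c("rare", "common"), form)
      sis <- ids[[paste0(other, fam)]]
      ingTaxa <- ids[[paste0(form, fam)]]
      outTaxa <- unlist(ids[grep(setdiff(c("A", "B"), fam), names(ids))],
                        use.names = FALSE)
      expected <- bruteForceClassify(col, ingTaxa, sis, outTaxa)
      got <- evaluateSite(aln, 1, grouping, ingroup = ing)
      expect_identical(got@classification, expected$classification,
                       info = paste(col, collapse = ""))
      expect_identical(got@weak, expected$weak, info = paste(col, collapse = ""))
    }
  }
})

test_that("summaries count calls per ingroup and average defining-class conservation", {
  fx <- makeCharSiteBenchmark()
  scan <- scanCharSites(fx$alignment, fx$grouping)
  s <- summarizeCalls(scan)
  cs <- s$counts[s$counts$ingroup == "SerRS:common", ]
  expect_identical(cs$symplesiomorphies, 4L)
  expect_identical(unname(s$familyMeans["SerRS"]), 92)
  expect_true(all(c("site", "profile.SerRS:common", "classification") %in% names(s$table)))

  # single call with percent 100
  one <- scan$calls[scan$calls$ingroup_pct == 100 &
                      scan$calls$classification == "symplesiomorphy", ][1, ]
  expect_identical(unname(summarizeCalls(one)$familyMeans), 100)

  # no calls at all
  empty <- summarizeCalls(scan$calls[0, ])
  expect_identical(nrow(empty$counts), 0L)
  expect_identical(length(empty$familyMeans), 0L)
})
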