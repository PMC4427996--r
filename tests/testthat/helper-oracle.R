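# Brute-force character-site enumerator, kept deliberately independent of
# the package kernel: it applies the relaxed definition literally, residue
# by residue, with no similarity-class merging (use it on columns whose
# residues are not co-classed) and no precomputation.
#
# col: named character vector (taxon -> residue); groups: list with
# ingroup/sister/outgroup taxon-id vectors. Returns
# list(classification, weak).
bruteForceClassify <- function(col, ingroup, sister, outgroup,
                               threshold = 0.5, minNonGap = 0.5) {
  share <- function(taxa, r) {
    x <- col[taxa]
    x <- x[x != "-" & x != "X"]
    if (!length(x)) return(0)
    sum(x == r) / length(x)
  }
  coverage <- function(taxa) mean(col[taxa] != "-")
  effective <- function(taxa) sum(col[taxa] != "-" & col[taxa] != "X")
  if (coverage(ingroup) < minNonGap || effective(ingroup) == 0 ||
      coverage(sister) < minNonGap || effective(sister) == 0 ||
      coverage(outgroup) < minNonGap || effective(outgroup) == 0)
    return(list(classification = "none", weak = FALSE))

  residues <- setdiff(unique(col), c("-", "X"))
  absentSister <- function(r) !any(col[sister] == r)
  outCount <- function(r) sum(col[outgroup] == r)
  for (r in residues)
    if (share(ingroup, r) > threshold && share(outgroup, r) > threshold &&
        absentSister(r))
      return(list(classification = "symplesiomorphy", weak = FALSE))
  for (r in residues)
    if (share(ingroup, r) > threshold && absentSister(r) && outCount(r) == 0)
      return(list(classification = "synapomorphy", weak = FALSE))
  maxOut <- max(vapply(residues, outCount, 0))
  for (r in residues)
    if (share(ingroup, r) > threshold && absentSister(r) &&
        share(outgroup, r) <= threshold &&
        outCount(r) > 0 && outCount(r) == maxOut)
      return(list(classification = "symplesiomorphy", weak = TRUE))
  list(classification = "none", weak = FALSE)
}

# random valid alignment for round-trip / property tests
randomAlignment <- function(nTaxa, nCols, gapProb = 0.1) {
  alphabet <- c(ParalogSites::AA_RESIDUES, "-", "X")
  probs <- c(rep((1 - gapProb - 0.02) / 20, 20), gapProb, 0.02)
  m <- matrix(sample(alphabet, nTaxa * nCols, replace = TRUE, prob = probs),
              nrow = nTaxa,
              dimnames = list(sprintf("tax%02d", seq_len(nTaxa)), NULL))
  ParalogSites::AaAlignment(m)
}

# 4-group grouping over explicitly supplied taxa
fourGroupGrouping <- function(commonA, rareA, commonB, rareB,
                              families = c("A", "B")) {
  ParalogSites::taxonGrouping(
    taxon = c(commonA, rareA, commonB, rareB),
    family = rep(c(families[1L], families[1L], families[2L], families[2L]),
                 c(length(commonA), length(rareA), length(commonB), length(rareB))),
    form = rep(c("common", "rare", "common", "rare"),
               c(length(commonA), length(rareA), length(commonB), length(rareB))))
}

# one-column alignment from per-group residue vectors (recycled to size)
columnAlignment <- function(commonA, rareA, commonB, rareB) {
  vals <- c(commonA, rareA, commonB, rareB)
  ids <- c(sprintf("cA%02d", seq_along(commonA)),
           sprintf("rA%02d", seq_along(rareA)),
           sprintf("cB%02d", seq_along(commonB)),
           sprintf("rB%02d", seq_along(rareB)))
  aln <- ParalogSites::AaAlignment(matrix(vals, ncol = 1L,
                                          dimnames = list(ids, NULL)))
  grouping <- fourGroupGrouping(ids[seq_along(commonA)],
                                ids[length(commonA) + seq_along(rareA)],
                                ids[length(commonA) + length(rareA) +
                                      seq_along(commonB)],
                                ids[length(commonA) + length(rareA) +
                                      length(commonB) + seq_along(rareB)])
  list(alignment = aln, grouping = grouping)
}
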