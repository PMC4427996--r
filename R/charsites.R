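#' Construct a similarity scheme
#'
#' @param classes named list of residue vectors, pairwise disjoint, each of
#'   size >= 2.
#' @return A [SimilarityScheme].
#' @export
similarityScheme <- function(classes) {
  new("SimilarityScheme", classes = lapply(classes, as.character))
}

#' The default physiochemical similarity classes
#'
#' Residue pairs/sets commonly treated as interchangeable in conservation
#' profiling: \code{{K,R}}, \code{{D,E}}, \code{{L,M,I,V}}, \code{{F,Y,W}},
#' \code{{S,T}}. Fully configurable via [similarityScheme()].
#'
#' @return A [SimilarityScheme].
#' @export
defaultSimilarityScheme <- function() {
  similarityScheme(list(
    KR = c("K", "R"),
    DE = c("D", "E"),
    LMIV = c("L", "M", "I", "V"),
    FYW = c("F", "Y", "W"),
    ST = c("S", "T")))
}

#' The default radicality super-categories
#'
#' Used by [radicality()] to decide whether an ingroup-vs-sister residue
#' difference is conservative (same physiochemical super-category) or
#' radical: aliphatic \code{{A,V,L,I,M,C}}, aromatic \code{{F,W,Y}}, polar
#' \code{{S,T,N,Q,G}}, positive \code{{K,R,H}}, negative \code{{D,E}}, and
#' proline on its own. Keeping aromatics apart from aliphatics makes an
#' aromatic-vs-aliphatic replacement (e.g. F vs L/M) radical, which matches
#' how such differences are read at slowly evolving positions.
#'
#' @return Named list of residue vectors covering the 20 amino acids.
#' @export
defaultRadicalityCategories <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M", "C"),
       aromatic = c("F", "W", "Y"),
       polar = c("S", "T", "N", "Q", "G"),
       positive = c("K", "R", "H"),
       negative = c("D", "E"),
       proline = "P")
}

#' Classify an amino-acid difference as radical or conservative
#'
#' Two residue classes are \code{"conservative"} when every residue of both
#' falls in the same super-category; anything else is \code{"radical"}.
#'
#' @param classA,classB residue classes, as character vectors of one-letter
#'   codes or \code{"/"}-joined strings (e.g. \code{"R/K"}).
#' @param categories named list of super-categories; default
#'   [defaultRadicalityCategories()].
#' @return \code{"radical"} or \code{"conservative"}.
#' @examples
#' radicality("G", "P")  # radical
#' radicality("D", "E")  # conservative
#' @export
radicality <- function(classA, classB, categories = defaultRadicalityCategories()) {
  splitClass <- function(x) {
    r <- unlist(strsplit(as.character(x), "/", fixed = TRUE), use.names = FALSE)
    bad <- setdiff(r, AA_RESIDUES)
    if (length(bad)) stopf("unknown residue: %s", paste(bad, collapse = ", "))
    r
  }
  catOf <- function(res) {
    hit <- vapply(categories, function(cat) all(res %in% cat), logical(1L))
    if (any(hit)) names(categories)[which(hit)[1L]] else NA_character_
  }
  ca <- catOf(splitClass(classA))
  cb <- catOf(splitClass(classB))
  if (!is.na(ca) && !is.na(cb) && ca == cb) "conservative" else "radical"
}

#' Construct character-site detection parameters
#'
#' Defaults encode the relaxed character-site definition: a defining
#' residue class must be carried by strictly more than 50\% of the ingroup
#' and (for a symplesiomorphy) strictly more than 50\% of the pooled
#' outgroup, while being absent from every sister-group taxon
#' (residue-level absence). Groups with more than half gaps at a column are
#' ineligible there. All threshold comparisons use raw fractions; rounding
#' is display-only.
#'
#' @param shareThreshold strict share threshold, default 0.5.
#' @param absenceScope \code{"residue"} (default) or \code{"class"}.
#' @param outgroupPooling \code{"pooled"} (default) or
#'   \code{"per-form-majority"}.
#' @param minNonGapFraction default 0.5.
#' @return A [CharSiteParams].
#' @export
charSiteParams <- function(shareThreshold = 0.5,
                           absenceScope = c("residue", "class"),
                           outgroupPooling = c("pooled", "per-form-majority"),
                           minNonGapFraction = 0.5) {
  new("CharSiteParams",
      shareThreshold = shareThreshold,
      absenceScope = match.arg(absenceScope),
      outgroupPooling = match.arg(outgroupPooling),
      minNonGapFraction = minNonGapFraction)
}

# residue counts of one group at one column
# returns list(res = named int over the 20 residues, nonGap, nEff, n)
.columnCounts <- function(colChars) {
  res <- tabulate(factor(colChars, levels = AA_RESIDUES), nbins = 20L)
  names(res) <- AA_RESIDUES
  nonGap <- sum(colChars != "-")
  list(res = res, nonGap = nonGap,
       nEff = nonGap - sum(colChars == "X"), n = length(colChars))
}

# aggregate residue counts into display classes:
# scheme classes merge only when >= 2 member residues are present
.aggregateClasses <- function(res, scheme) {
  counts <- res[res > 0L]
  classes <- list()
  for (members in scheme@classes) {
    present <- members[members %in% names(counts)]
    if (length(present) >= 2L) {
      ord <- order(-counts[present], present)
      lab <- paste(present[ord], collapse = "/")
      classes[[lab]] <- present
      counts <- counts[setdiff(names(counts), present)]
      counts[lab] <- sum(res[present])
    }
  }
  for (r in setdiff(names(counts), names(classes))) classes[[r]] <- r
  list(counts = counts, residues = classes)
}

.makeProfile <- function(label, cc, scheme, minNonGapFraction) {
  agg <- .aggregateClasses(cc$res, scheme)
  eligible <- cc$n > 0L && (cc$nonGap / cc$n) >= minNonGapFraction && cc$nEff > 0L
  if (length(agg$counts)) {
    ord <- order(-agg$counts, names(agg$counts))
    dom <- names(agg$counts)[ord[1L]]
    share <- unname(agg$counts[dom]) / cc$nEff
  } else {
    dom <- NA_character_
    share <- NA_real_
  }
  new("GroupProfile", label = label, nTaxa = as.integer(cc$n),
      nonGap = as.integer(cc$nonGap), nEffective = as.integer(cc$nEff),
      residueCounts = as.integer(cc$res) |> stats::setNames(AA_RESIDUES),
      classCounts = as.integer(agg$counts) |> stats::setNames(names(agg$counts)),
      classResidues = agg$residues,
      dominantClass = dom, dominantShare = share, eligible = eligible)
}

#' Format a group profile for reporting
#'
#' Ineligible profiles render as \code{"-"}; profiles whose dominant class
#' exceeds 50\% as \code{"<class>(<percent>)"} (percent rounded half-up over
#' non-gap non-X residues); anything else as \code{"not conserved"}.
#'
#' @param profile a [GroupProfile].
#' @return Character string.
#' @export
formatProfile <- function(profile) {
  if (!profile@eligible || is.na(profile@dominantClass)) return("-")
  if (profile@dominantShare > 0.5)
    sprintf("%s(%d)", profile@dominantClass,
            as.integer(roundHalfUp(100 * profile@dominantShare)))
  else "not conserved"
}

setMethod("show", "GroupProfile", function(object) {
  cat(sprintf("GroupProfile '%s': %s (%d/%d non-gap)\n", object@label,
              formatProfile(object), object@nonGap, object@nTaxa))
})

#' Residue profile of one taxon group at one column
#'
#' Counts residues over non-gap, non-\code{X} cells of the group at the
#' column, merges physiochemically similar residues into a class when at
#' least two class members are present, and reports the dominant class and
#' its share. A group whose non-gap coverage is below
#' \code{minNonGapFraction} is flagged ineligible.
#'
#' @param alignment an [AaAlignment].
#' @param column 1-based column coordinate.
#' @param taxa non-empty character vector of taxon ids.
#' @param scheme a [SimilarityScheme].
#' @param minNonGapFraction eligibility coverage threshold, default 0.5.
#' @param label profile label.
#' @return A [GroupProfile].
#' @examples
#' aln <- AaAlignment(c(a = "K", b = "R", c = "K", d = "G"))
#' formatProfile(groupResidueProfile(aln, 1, c("a", "b", "c", "d")))  # "K/R(75)"
#' @export
groupResidueProfile <- function(alignment, column, taxa,
                                scheme = defaultSimilarityScheme(),
                                minNonGapFraction = 0.5, label = "group") {
  if (!length(taxa)) stopf("empty taxa set")
  missing <- setdiff(taxa, taxonIds(alignment))
  if (length(missing))
    stopf("taxa not in alignment: %s", paste(missing, collapse = ", "))
  if (column < 1L || column > nColumns(alignment))
    stopf("column %d out of range [1, %d]", column, nColumns(alignment))
  cc <- .columnCounts(alignment@seqs[taxa, column])
  .makeProfile(label, cc, scheme, minNonGapFraction)
}

# ---- classification kernel ------------------------------------------------
#
# Shared by evaluateSite() and scanCharSites(). Works purely on per-group
# residue counts at one column. Returns the classification decision.
#
# Candidate defining classes: every residue whose ingroup share (over
# non-gap non-X) strictly exceeds the threshold, plus every similarity
# class with >= 2 member residues present in the ingroup whose summed share
# exceeds it. Candidates are tried in order of decreasing ingroup share
# (ties alphabetical). Priority: full symplesiomorphy, then synapomorphy,
# then weak symplesiomorphy (defining class misses the outgroup threshold
# but is the outgroup's plurality class).
.classifyColumn <- function(cIn, cSis, cOutList, scheme, params) {
  thr <- params@shareThreshold
  none <- function(reason) list(classification = "none",
                                definingClass = NA_character_,
                                definingResidues = character(),
                                ingroupShare = NA_real_,
                                outgroupShare = NA_real_,
                                weak = FALSE, reason = reason)

  eligible <- function(cc) cc$n > 0L &&
    (cc$nonGap / cc$n) >= params@minNonGapFraction && cc$nEff > 0L
  cOut <- list(res = Reduce(`+`, lapply(cOutList, `[[`, "res")),
               nonGap = sum(vapply(cOutList, function(x) as.numeric(x$nonGap), 0)),
               nEff = sum(vapply(cOutList, function(x) as.numeric(x$nEff), 0)),
               n = sum(vapply(cOutList, function(x) as.numeric(x$n), 0)))
  if (!eligible(cIn)) return(none("ineligible_ingroup"))
  if (!eligible(cSis)) return(none("ineligible_sister"))
  if (!eligible(cOut)) return(none("ineligible_outgroup"))

  # candidate defining classes from the ingroup
  present <- names(cIn$res)[cIn$res > 0L]
  cand <- lapply(present, function(r) r)
  for (members in scheme@classes) {
    hit <- members[members %in% present]
    if (length(hit) >= 2L) cand <- c(cand, list(hit))
  }
  shares <- vapply(cand, function(rs) sum(cIn$res[rs]) / cIn$nEff, numeric(1L))
  keep <- shares > thr
  if (!any(keep)) return(none("no_candidate"))
  cand <- cand[keep]; shares <- shares[keep]
  labs <- vapply(cand, function(rs) paste(sort(rs), collapse = "/"), "")
  ord <- order(-shares, labs)
  cand <- cand[ord]; shares <- shares[ord]

  fullClass <- function(rs) {
    # widen to the whole scheme class for class-scope absence
    for (members in scheme@classes) if (any(rs %in% members))
      return(unique(c(rs, members)))
    rs
  }
  outShareOf <- function(rs) {
    if (params@outgroupPooling == "pooled") {
      if (cOut$nEff == 0L) return(0)
      sum(cOut$res[rs]) / cOut$nEff
    } else {
      sizes <- vapply(cOutList, function(x) as.numeric(x$n), 0)
      major <- cOutList[[which.max(sizes)]]
      if (major$nEff == 0L) return(0)
      sum(major$res[rs]) / major$nEff
    }
  }

  call <- function(rs, classification, weak = FALSE) {
    ord2 <- order(-cIn$res[rs], rs)
    list(classification = classification,
         definingClass = paste(rs[ord2], collapse = "/"),
         definingResidues = rs,
         ingroupShare = sum(cIn$res[rs]) / cIn$nEff,
         outgroupShare = outShareOf(rs),
         weak = weak, reason = NA_character_)
  }

  synap <- NULL
  weakCall <- NULL
  outAgg <- .aggregateClasses(cOut$res, scheme)
  for (k in seq_along(cand)) {
    rs <- cand[[k]]
    absSet <- if (params@absenceScope == "class") fullClass(rs) else rs
    if (sum(cSis$res[absSet]) > 0L) next  # a single sister carrier vetoes
    outShare <- outShareOf(rs)
    if (outShare > thr) return(call(rs, "symplesiomorphy"))
    if (is.null(synap) && sum(cOut$res[absSet]) == 0L)
      synap <- call(rs, "synapomorphy")
    if (is.null(weakCall) && length(outAgg$counts)) {
      outCount <- sum(cOut$res[rs])
      if (outCount > 0L && outCount == max(outAgg$counts))
        weakCall <- call(rs, "symplesiomorphy", weak = TRUE)
    }
  }
  if (!is.null(synap)) return(synap)
  if (!is.null(weakCall)) return(weakCall)
  none("no_call")
}

# resolve ingroup/sister/outgroup taxon sets for an ingroup label
.roles <- function(grouping, ingroup) {
  g <- resolveGroup(grouping, ingroup)
  a <- grouping@assignments
  otherForm <- setdiff(c("rare", "common"), g$form)
  sister <- a$taxon[a$family == g$family & a$form == otherForm]
  if (!length(sister))
    stopf("sister group %s:%s has no taxa", g$family, otherForm)
  outFams <- setdiff(unique(a$family), g$family)
  if (!length(outFams))
    stopf("no outgroup family for ingroup %s:%s", g$family, g$form)
  outForms <- lapply(outFams, function(f) {
    forms <- unique(a$form[a$family == f])
    lapply(forms, function(fo) a$taxon[a$family == f & a$form == fo])
  })
  outForms <- unlist(outForms, recursive = FALSE)
  if (!length(outForms)) stopf("outgroup is empty")
  list(family = g$family, form = g$form, label = paste(g$family, g$form, sep = ":"),
       ingroup = g$taxa, sister = sister, outgroupForms = outForms)
}

#' Classify one alignment column for one ingroup
#'
#' Applies the relaxed character-site definition at a single column. With
#' ingroup = one (family, form) pair, sister group = the other form of the
#' same family, and outgroup = the whole other family (pooled across its
#' forms by default): the column is a \emph{symplesiomorphy} when some
#' residue class is carried by more than the threshold share of the ingroup
#' and of the outgroup while being absent from every sister-group taxon,
#' and a \emph{synapomorphy} when the class clears the ingroup threshold
#' and is absent from the entire sister group \emph{and} outgroup. A call
#' whose defining class misses the outgroup threshold but is still the
#' outgroup's plurality class is emitted as a weak symplesiomorphy
#' (\code{weak = TRUE}); weak calls are excluded from headline counts.
#'
#' @param alignment an [AaAlignment].
#' @param column 1-based column coordinate.
#' @param grouping a [TaxonGrouping] covering the alignment.
#' @param scheme a [SimilarityScheme].
#' @param params a [CharSiteParams].
#' @param ingroup \code{"family:form"} or \code{c(family, form)}.
#' @return A [CharSiteCall] carrying the four group profiles.
#' @seealso [scanCharSites()] for whole-alignment scans.
#' @export
evaluateSite <- function(alignment, column, grouping,
                         scheme = defaultSimilarityScheme(),
                         params = charSiteParams(), ingroup) {
  if (column < 1L || column > nColumns(alignment))
    stopf("column %d out of range [1, %d]", column, nColumns(alignment))
  roles <- .roles(grouping, ingroup)
  m <- alignment@seqs
  cIn <- .columnCounts(m[roles$ingroup, column])
  cSis <- .columnCounts(m[roles$sister, column])
  cOutList <- lapply(roles$outgroupForms, function(tx) .columnCounts(m[tx, column]))
  res <- .classifyColumn(cIn, cSis, cOutList, scheme, params)

  labels <- groupLabels(grouping)
  profiles <- lapply(labels, function(lab) {
    tx <- resolveGroup(grouping, lab)$taxa
    .makeProfile(lab, .columnCounts(m[tx, column]), scheme,
                 params@minNonGapFraction)
  })
  names(profiles) <- labels

  rad <- NA_character_
  if (res$classification != "none") {
    sisProf <- .makeProfile("sister", cSis, scheme, params@minNonGapFraction)
    if (sisProf@eligible && !is.na(sisProf@dominantClass))
      rad <- radicality(res$definingResidues,
                        sisProf@classResidues[[sisProf@dominantClass]])
  }
  new("CharSiteCall", column = as.integer(column), ingroup = roles$label,
      classification = res$classification,
      definingClass = res$definingClass,
      definingResidues = res$definingResidues,
      ingroupShare = res$ingroupShare, outgroupShare = res$outgroupShare,
      profiles = profiles, radicality = rad, weak = res$weak,
      reason = res$reason %||% NA_character_)
}

#' Scan every alignment column for character sites
#'
#' One pass over all columns for each requested ingroup, using the same
#' classification kernel as [evaluateSite()] but with per-group residue
#' counts precomputed for speed. Only columns with a non-"none"
#' classification are returned, sorted by column.
#'
#' @param alignment an [AaAlignment].
#' @param grouping a [TaxonGrouping]; excluded taxa never enter any count.
#' @param scheme a [SimilarityScheme].
#' @param params a [CharSiteParams].
#' @param ingroups character vector of \code{"family:form"} labels; default
#'   all groups present in the grouping.
#' @return A list of class \code{"charSiteScan"} with elements
#'   \describe{
#'     \item{calls}{data.frame: \code{column}, \code{ingroup},
#'       \code{classification}, \code{defining_class},
#'       \code{ingroup_pct}, \code{outgroup_pct}, \code{radicality},
#'       \code{weak}, plus one \code{profile.<group>} column per group.}
#'     \item{counts}{data.frame of per-ingroup symplesiomorphy (non-weak),
#'       synapomorphy and weak counts.}
#'     \item{params, scheme}{the settings used.}
#'   }
#' @export
scanCharSites <- function(alignment, grouping,
                          scheme = defaultSimilarityScheme(),
                          params = charSiteParams(),
                          ingroups = groupLabels(grouping)) {
  validateGrouping(grouping, alignment, unknownTaxa = "warn")
  m <- alignment@seqs
  nc <- ncol(m)
  labels <- groupLabels(grouping)

  groupCounts <- lapply(labels, function(lab) {
    tx <- resolveGroup(grouping, lab)$taxa
    sub <- m[tx, , drop = FALSE]
    res <- matrix(0L, nrow = 20L, ncol = nc, dimnames = list(AA_RESIDUES, NULL))
    for (r in AA_RESIDUES) res[r, ] <- colSums(sub == r)
    list(res = res, nonGap = colSums(sub != "-"),
         nEff = colSums(sub != "-" & sub != "X"), n = length(tx))
  })
  names(groupCounts) <- labels
  countsAt <- function(lab, j) {
    gc <- groupCounts[[lab]]
    list(res = gc$res[, j], nonGap = gc$nonGap[j], nEff = gc$nEff[j], n = gc$n)
  }

  rows <- list()
  for (ing in ingroups) {
    roles <- .roles(grouping, ing)
    sisLab <- paste(roles$family, setdiff(c("rare", "common"), roles$form),
                    sep = ":")
    outLabs <- labels[vapply(strsplit(labels, ":", fixed = TRUE),
                             function(x) x[1L] != roles$family, logical(1L))]
    for (j in seq_len(nc)) {
      res <- .classifyColumn(countsAt(roles$label, j), countsAt(sisLab, j),
                             lapply(outLabs, countsAt, j), scheme, params)
      if (res$classification == "none") next
      profs <- vapply(labels, function(lab) {
        formatProfile(.makeProfile(lab, countsAt(lab, j), scheme,
                                   params@minNonGapFraction))
      }, "")
      sisProf <- .makeProfile(sisLab, countsAt(sisLab, j), scheme,
                              params@minNonGapFraction)
      rad <- if (sisProf@eligible && !is.na(sisProf@dominantClass))
        radicality(res$definingResidues,
                   sisProf@classResidues[[sisProf@dominantClass]])
      else NA_character_
      row <- data.frame(column = j, ingroup = roles$label,
                        classification = res$classification,
                        defining_class = res$definingClass,
                        ingroup_pct = roundHalfUp(100 * res$ingroupShare),
                        outgroup_pct = roundHalfUp(100 * res$outgroupShare),
                        radicality = rad, weak = res$weak,
                        stringsAsFactors = FALSE)
      for (lab in labels) row[[paste0("profile.", lab)]] <- unname(profs[lab])
      rows[[length(rows) + 1L]] <- row
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(), ingroup = character(),
               classification = character(), defining_class = character(),
               ingroup_pct = numeric(), outgroup_pct = numeric(),
               radicality = character(), weak = logical(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$column, calls$ingroup), , drop = FALSE]
  rownames(calls) <- NULL

  counts <- do.call(rbind, lapply(ingroups, function(ing) {
    sub <- calls[calls$ingroup == ing, , drop = FALSE]
    data.frame(ingroup = ing,
               symplesiomorphies = sum(sub$classification == "symplesiomorphy" & !sub$weak),
               synapomorphies = sum(sub$classification == "synapomorphy"),
               weak = sum(sub$weak),
               stringsAsFactors = FALSE)
  }))
  structure(list(calls = calls, counts = counts, params = params,
                 scheme = scheme),
            class = "charSiteScan")
}

#' @export
print.charSiteScan <- function(x, ...) {
  cat(sprintf("charSiteScan: %d call(s)\n", nrow(x$calls)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Summarise character-site calls
#'
#' Produces per-ingroup headline counts (weak calls reported separately,
#' never counted), the per-family mean conservation of symplesiomorphy
#' sites (the mean, over each family's non-weak symplesiomorphy calls, of
#' the defining class's share within its own ingroup, as a rounded
#' percent), and a report table laid out one row per called site with the
#' four group profiles.
#'
#' @param scan result of [scanCharSites()] (or its \code{calls} data.frame).
#' @return A list with elements \code{counts}, \code{familyMeans} (named
#'   numeric, \code{NA} for a family without symplesiomorphy calls) and
#'   \code{table}.
#' @export
summarizeCalls <- function(scan) {
  calls <- if (is.data.frame(scan)) scan else scan$calls
  ingroups <- unique(calls$ingroup)
  counts <- if (length(ingroups)) {
    do.call(rbind, c(lapply(ingroups, function(ing) {
      sub <- calls[calls$ingroup == ing, , drop = FALSE]
      data.frame(ingroup = ing,
                 symplesiomorphies = sum(sub$classification == "symplesiomorphy" & !sub$weak),
                 synapomorphies = sum(sub$classification == "synapomorphy"),
                 weak = sum(sub$weak),
                 stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  } else {
    data.frame(ingroup = character(), symplesiomorphies = integer(),
               synapomorphies = integer(), weak = integer())
  }

  fams <- unique(vapply(strsplit(calls$ingroup, ":", fixed = TRUE), `[[`, "", 1L))
  familyMeans <- stats::setNames(vapply(fams, function(f) {
    sub <- calls[startsWith(calls$ingroup, paste0(f, ":")) &
                   calls$classification == "symplesiomorphy" & !calls$weak, ,
                 drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    roundHalfUp(mean(sub$ingroup_pct))
  }, numeric(1L)), fams)

  profCols <- grep("^profile\\.", names(calls), value = TRUE)
  tab <- calls[, c("column", profCols, "classification", "defining_class",
                   "radicality", "weak"), drop = FALSE]
  names(tab)[1L] <- "site"
  list(counts = counts, familyMeans = familyMeans, table = tab)
}

#' Write a character-site report table to TSV
#'
#' @param scan a \code{charSiteScan} or [summarizeCalls()] result.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeCharSiteReport <- function(scan, path) {
  tab <- if (!is.null(scan$table)) scan$table else summarizeCalls(scan)$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
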