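#' Construct a SiteMask
#'
#' @param columns 1-based master-alignment coordinates (sorted and
#'   deduplicated for you).
#' @param label mask label (e.g. \code{"shared"}, \code{"SerRS"}).
#' @return A [SiteMask].
#' @export
siteMask <- function(columns, label = "mask") {
  cols <- sort(unique(as.integer(columns)))
  new("SiteMask", columns = cols, label = as.character(label))
}

#' Read a per-column alignment-confidence score table
#'
#' Two dialects are understood. \code{"guidance"} mimics GUIDANCE's
#' column-score output: tab- or whitespace-separated \code{(column, score)}
#' pairs, with \code{#}-comment lines and an optional non-numeric header
#' line tolerated. \code{"plain"} is two unlabeled whitespace-separated
#' columns. Scores must lie in [0, 1]; a violation reports its line number.
#' When \code{nColumns} is given, columns without a score are imputed as 0
#' and recorded in the returned table.
#'
#' @param path score file.
#' @param dialect \code{"guidance"} (default) or \code{"plain"}.
#' @param nColumns optional master-alignment width for bounds checking and
#'   imputation of missing columns.
#' @return A [SiteScoreTable] with \code{source = "external"}.
#' @seealso [surrogateColumnScores()], [maskFromScores()]
#' @export
readSiteScores <- function(path, dialect = c("guidance", "plain"),
                           nColumns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "guidance" && length(lines)) {
    # tolerate one header line of column names
    first <- strsplit(trimws(lines[1L]), "[\t ]+")[[1L]]
    if (suppressWarnings(anyNA(as.numeric(first)))) {
      lines <- lines[-1L]
      lineno <- lineno[-1L]
    }
  }
  if (!length(lines)) stopf("no score rows in %s", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(parts) < 2L))
    stopf("malformed score row at line %d of %s",
          lineno[which(lengths(parts) < 2L)[1L]], path)
  cols <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  scores <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(cols) | is.na(scores))
  if (length(bad))
    stopf("unparseable score row at line %d of %s", lineno[bad[1L]], path)
  oob <- which(scores < 0 | scores > 1)
  if (length(oob))
    stopf("score %g outside [0, 1] at line %d of %s",
          scores[oob[1L]], lineno[oob[1L]], path)
  if (anyDuplicated(cols))
    stopf("duplicate column coordinate %d in %s", cols[duplicated(cols)][1L], path)
  ord <- order(cols)
  cols <- cols[ord]; scores <- scores[ord]
  imputed <- integer()
  if (!is.null(nColumns)) {
    if (any(cols > nColumns))
      stopf("score for column %d beyond alignment width %d",
            max(cols), nColumns)
    imputed <- setdiff(seq_len(nColumns), cols)
    if (length(imputed)) {
      message(sprintf("%d column(s) without a score imputed as 0", length(imputed)))
      cols <- c(cols, imputed)
      scores <- c(scores, rep(0, length(imputed)))
      ord <- order(cols)
      cols <- cols[ord]; scores <- scores[ord]
    }
  }
  new("SiteScoreTable", columns = as.integer(cols), scores = scores,
      source = "external", imputed = as.integer(sort(imputed)))
}

#' Write a score table to TSV
#'
#' @param scores a [SiteScoreTable].
#' @param path output TSV (columns \code{column}, \code{score}).
#' @return \code{path}, invisibly.
#' @export
writeSiteScores <- function(scores, path) {
  utils::write.table(data.frame(column = scores@columns, score = scores@scores),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Surrogate per-column alignment-quality scores
#'
#' A stand-in column scorer for use when no external (GUIDANCE-style)
#' confidence file is available. For each column, over the chosen taxa:
#' score = (mean pairwise identity among non-gap residue pairs) x (non-gap
#' fraction). \code{"X"} counts as coverage but never as an identity match
#' or mismatch. Columns with fewer than two non-gap residues score 0.
#' Scores are guaranteed to lie in [0, 1].
#'
#' @param alignment an [AaAlignment].
#' @param taxa optional subset of taxon ids (>= 2) over which to score;
#'   default all taxa. Scoring a clade's taxa yields the clade-specific
#'   quality track used for decomposition.
#' @return A [SiteScoreTable] with \code{source = "surrogate"}.
#' @examples
#' aln <- AaAlignment(c(a = "AA", b = "AC", c = "-A", d = "-A"))
#' siteScores(surrogateColumnScores(aln))
#' @export
surrogateColumnScores <- function(alignment, taxa = NULL) {
  m <- alignment@seqs
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(m))
    if (length(missing))
      stopf("taxa not in alignment: %s", paste(missing, collapse = ", "))
    m <- m[taxa, , drop = FALSE]
  }
  if (nrow(m) < 2L) stopf("need at least 2 taxa to score columns")
  n <- nrow(m)
  scores <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nongap <- col != "-"
    res <- col[nongap & col != "X"]
    if (length(res) < 2L) return(0)
    counts <- tabulate(factor(res, levels = AA_RESIDUES), nbins = 20L)
    pairs_same <- sum(counts * (counts - 1L)) / 2
    pairs_all <- length(res) * (length(res) - 1L) / 2
    identity <- pairs_same / pairs_all
    identity * (sum(nongap) / n)
  }, numeric(1L))
  new("SiteScoreTable", columns = seq_len(ncol(m)), scores = scores,
      source = "surrogate", imputed = integer())
}

#' Threshold a score table into a site mask
#'
#' Keeps every scored column whose confidence is at least \code{cutoff}.
#' A cutoff no column reaches yields an empty mask with a warning.
#'
#' @param scores a [SiteScoreTable].
#' @param cutoff in [0, 1].
#' @param label label for the resulting [SiteMask].
#' @return A [SiteMask].
#' @export
maskFromScores <- function(scores, cutoff, label = "mask") {
  stopifnot(is(scores, "SiteScoreTable"))
  if (cutoff < 0 || cutoff > 1) stopf("cutoff must lie in [0, 1]")
  keep <- scores@columns[scores@scores >= cutoff]
  if (!length(keep))
    warnf("no column reaches score cutoff %g; mask '%s' is empty", cutoff, label)
  new("SiteMask", columns = as.integer(keep), label = as.character(label))
}

#' Read a site mask from TSV
#'
#' One coordinate per row (first column; header and \code{#} comments
#' tolerated).
#'
#' @param path TSV/one-column file of 1-based coordinates.
#' @param label mask label.
#' @return A [SiteMask].
#' @export
readSiteMask <- function(path, label = "mask") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  first <- vapply(strsplit(trimws(lines), "[\t ]+"), `[[`, "", 1L)
  vals <- suppressWarnings(as.integer(first))
  if (length(vals) && is.na(vals[1L])) vals <- vals[-1L]  # header line
  if (anyNA(vals)) stopf("unparseable coordinate in %s", path)
  siteMask(vals, label)
}
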