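#' Construct a TaxonGrouping
#'
#' @param taxon,family,form parallel character vectors assigning each taxon
#'   to a family and a form (\code{"rare"} or \code{"common"}).
#' @param excluded character vector of taxa outside the analysis.
#' @return A [TaxonGrouping].
#' @examples
#' g <- taxonGrouping(c("a", "b"), c("SerRS", "SerRS"), c("rare", "common"))
#' groupTaxa(g, "SerRS", "rare")
#' @export
taxonGrouping <- function(taxon, family, form, excluded = character()) {
  new("TaxonGrouping",
      assignments = data.frame(taxon = as.character(taxon),
                               family = as.character(family),
                               form = as.character(form),
                               stringsAsFactors = FALSE),
      excluded = as.character(excluded))
}

#' Read a taxon grouping table
#'
#' Reads a TSV with header columns \code{taxon}, \code{family}, \code{form}.
#' Rows whose form is \code{"excluded"} land in the excluded set. If an
#' alignment is supplied the grouping is validated against it (see
#' [validateGrouping()]).
#'
#' @param path TSV file.
#' @param alignment optional [AaAlignment] to validate against.
#' @param unknownTaxa what to do with table taxa absent from the alignment:
#'   \code{"warn"} (default) or \code{"error"}.
#' @return A [TaxonGrouping].
#' @export
readGroupTable <- function(path, alignment = NULL,
                           unknownTaxa = c("warn", "error")) {
  unknownTaxa <- match.arg(unknownTaxa)
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           strip.white = TRUE)
  need <- c("taxon", "family", "form")
  if (!all(need %in% names(tab)))
    stopf("group table must have columns: %s", paste(need, collapse = ", "))
  excl <- tab$form == "excluded"
  grouping <- taxonGrouping(tab$taxon[!excl], tab$family[!excl],
                            tab$form[!excl], excluded = tab$taxon[excl])
  if (!is.null(alignment))
    validateGrouping(grouping, alignment, unknownTaxa = unknownTaxa)
  grouping
}

#' Validate a grouping against an alignment
#'
#' Every alignment taxon must be either assigned or excluded (an error
#' listing the missing taxa otherwise); grouping taxa absent from the
#' alignment produce a warning, or an error when \code{unknownTaxa =
#' "error"}.
#'
#' @param grouping a [TaxonGrouping].
#' @param alignment an [AaAlignment].
#' @param unknownTaxa \code{"warn"} or \code{"error"}.
#' @return \code{grouping}, invisibly.
#' @export
validateGrouping <- function(grouping, alignment,
                             unknownTaxa = c("warn", "error")) {
  unknownTaxa <- match.arg(unknownTaxa)
  validObject(grouping)
  known <- c(grouping@assignments$taxon, grouping@excluded)
  aln_taxa <- taxonIds(alignment)
  missing <- setdiff(aln_taxa, known)
  if (length(missing))
    stopf("alignment taxa absent from the group table: %s",
          paste(missing, collapse = ", "))
  extra <- setdiff(known, aln_taxa)
  if (length(extra)) {
    msg <- sprintf("group-table taxa absent from the alignment: %s",
                   paste(extra, collapse = ", "))
    if (unknownTaxa == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  invisible(grouping)
}

#' Write a grouping to TSV
#'
#' Inverse of [readGroupTable()]: assigned rows keep their form, excluded
#' taxa are written with form \code{"excluded"} and an empty family.
#'
#' @param grouping a [TaxonGrouping].
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeGroupTable <- function(grouping, path) {
  a <- grouping@assignments
  if (length(grouping@excluded))
    a <- rbind(a, data.frame(taxon = grouping@excluded, family = "",
                             form = "excluded", stringsAsFactors = FALSE))
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# all (family, form) pairs present, as "family:form" labels in table order
groupLabels <- function(grouping) {
  a <- grouping@assignments
  unique(paste(a$family, a$form, sep = ":"))
}

# resolve "family:form" (or c(family, form)) into its taxa; error if empty
resolveGroup <- function(grouping, ingroup) {
  if (length(ingroup) == 1L) ingroup <- strsplit(ingroup, ":", fixed = TRUE)[[1L]]
  if (length(ingroup) != 2L)
    stopf("ingroup must be 'family:form' or c(family, form)")
  taxa <- groupTaxa(grouping, ingroup[1L], ingroup[2L])
  if (!length(taxa))
    stopf("group %s:%s has no taxa", ingroup[1L], ingroup[2L])
  list(family = ingroup[1L], form = ingroup[2L], taxa = taxa)
}
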