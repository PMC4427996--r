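#' Construct an AaAlignment
#'
#' Builds a validated [AaAlignment] from either a named character vector of
#' aligned sequences (one string per taxon) or a taxa-by-columns character
#' matrix with row names. Input is case-normalised to upper case; any other
#' deviation from the alphabet (20 amino acids, \code{"-"}, \code{"X"}) is
#' an error.
#'
#' @param x named character vector of equal-length aligned sequences, or a
#'   character matrix of single residues with taxon row names.
#' @return An [AaAlignment].
#' @examples
#' aln <- AaAlignment(c(t1 = "AC-D", t2 = "acdd"))
#' nColumns(aln)
#' @export
AaAlignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stopf("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      off <- names(x)[lens != lens[1L]][1L]
      stopf("ragged alignment: taxon '%s' has length %d, expected %d",
            off, nchar(x[[off]]), lens[1L])
    }
    m <- matrix(toupper(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)),
                nrow = length(x), byrow = TRUE,
                dimnames = list(names(x), NULL))
  }
  new("AaAlignment", seqs = m)
}

#' Read a protein multiple sequence alignment from FASTA
#'
#' Reads FASTA via Biostrings, case-normalises, and validates the result as
#' an [AaAlignment]: equal row lengths (ragged input names the offending
#' taxon), unique non-empty identifiers, characters restricted to the 20
#' amino acids plus \code{"-"} and \code{"X"} (violations are reported with
#' taxon and column). Record order is preserved; the identifier is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file with at least 2 records.
#' @return An [AaAlignment].
#' @seealso [writeAlignment()]
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ss <- Biostrings::readBStringSet(path)  # BString: no alphabet coercion yet
  if (length(ss) < 2L)
    stopf("alignment FASTA must contain at least 2 records, found %d", length(ss))
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), ids)
  AaAlignment(seqs)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' FASTA output round-trips exactly through [readFastaAlignment()]. The
#' relaxed PHYLIP writer emits the usual \code{"<ntaxa> <ncolumns>"} header
#' and does not truncate names; whitespace inside names is replaced by
#' \code{"_"}, and an error is raised if that sanitisation makes two names
#' collide.
#'
#' @param alignment an [AaAlignment].
#' @param path output file.
#' @param format \code{"fasta"} (default) or \code{"phylip-relaxed"}.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(alignment, path, format = c("fasta", "phylip-relaxed")) {
  stopifnot(is(alignment, "AaAlignment"))
  validObject(alignment)
  format <- match.arg(format)
  m <- alignment@seqs
  seqs <- apply(m, 1L, paste, collapse = "")
  if (format == "fasta") {
    ss <- Biostrings::AAStringSet(seqs)
    names(ss) <- rownames(m)
    Biostrings::writeXStringSet(ss, filepath = path)
  } else {
    nm <- gsub("\\s+", "_", rownames(m))
    if (anyDuplicated(nm))
      stopf("PHYLIP name collision after sanitisation: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
    lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
               sprintf("%s  %s", format(nm, width = max(nchar(nm))), seqs))
    writeLines(lines, path)
  }
  invisible(path)
}

# column subset preserving taxa; used by decomposition
alignmentColumns <- function(alignment, columns) {
  m <- alignment@seqs[, columns, drop = FALSE]
  dimnames(m) <- list(rownames(alignment@seqs), NULL)
  new("AaAlignment", seqs = m)
}
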