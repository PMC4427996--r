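#' @name ParalogSites-accessors
#' @title Accessors for the core classes
#'
#' @description
#' \code{taxonIds()} returns the taxon identifiers of an alignment;
#' \code{nTaxa()} and \code{nColumns()} its dimensions;
#' \code{alignmentMatrix()} the underlying taxa-by-columns character matrix;
#' \code{maskColumns()} a mask's 1-based coordinates; \code{maskLabel()} its
#' label; \code{siteScores()} the score vector of a [SiteScoreTable] named by
#' column; \code{groupTaxa()} the taxon ids of one (family, form) group of a
#' [TaxonGrouping]; \code{provenance()} the column provenance table of a
#' [DecomposedAlignment].
#'
#' @param x the object.
#' @param ... further arguments for methods.
#' @return See each accessor's description.
NULL

#' @rdname ParalogSites-accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("maskColumns", function(x) standardGeneric("maskColumns"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @rdname ParalogSites-accessors
#' @param family,form group selectors for \code{groupTaxa}.
#' @export
setGeneric("groupTaxa", function(x, family, form) standardGeneric("groupTaxa"))

#' @rdname ParalogSites-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ParalogSites-accessors
#' @export
setMethod("taxonIds", "AaAlignment", function(x) rownames(x@seqs))

#' @rdname ParalogSites-accessors
#' @export
setMethod("nTaxa", "AaAlignment", function(x) nrow(x@seqs))

#' @rdname ParalogSites-accessors
#' @export
setMethod("nColumns", "AaAlignment", function(x) ncol(x@seqs))

#' @rdname ParalogSites-accessors
#' @export
setMethod("alignmentMatrix", "AaAlignment", function(x) x@seqs)

#' @rdname ParalogSites-accessors
#' @export
setMethod("maskColumns", "SiteMask", function(x) x@columns)

#' @rdname ParalogSites-accessors
#' @export
setMethod("maskLabel", "SiteMask", function(x) x@label)

#' @rdname ParalogSites-accessors
#' @export
setMethod("siteScores", "SiteScoreTable", function(x) {
  stats::setNames(x@scores, x@columns)
})

#' @rdname ParalogSites-accessors
#' @export
setMethod("groupTaxa", "TaxonGrouping", function(x, family, form) {
  a <- x@assignments
  a$taxon[a$family == family & a$form == form]
})

#' @rdname ParalogSites-accessors
#' @export
setMethod("provenance", "DecomposedAlignment", function(x) x@provenance)

setMethod("show", "AaAlignment", function(object) {
  cat(sprintf("AaAlignment: %d taxa x %d columns\n",
              nTaxa(object), nColumns(object)))
  ids <- taxonIds(object)
  shown <- utils::head(ids, 3L)
  cat("  taxa:", paste(shown, collapse = ", "),
      if (length(ids) > 3L) sprintf("... (%d more)", length(ids) - 3L) else "",
      "\n")
})

setMethod("show", "TaxonGrouping", function(object) {
  a <- object@assignments
  cat(sprintf("TaxonGrouping: %d assigned taxa, %d excluded\n",
              nrow(a), length(object@excluded)))
  if (nrow(a)) {
    tab <- table(a$family, a$form)
    print(tab)
  }
})

setMethod("show", "SiteMask", function(object) {
  cat(sprintf("SiteMask '%s': %d columns\n", object@label,
              length(object@columns)))
})

setMethod("show", "SiteScoreTable", function(object) {
  cat(sprintf("SiteScoreTable (%s): %d columns scored", object@source,
              length(object@columns)))
  if (length(object@imputed))
    cat(sprintf(", %d imputed as 0", length(object@imputed)))
  cat("\n")
})

setMethod("show", "PartitionPlan", function(object) {
  cat(sprintf("PartitionPlan: %d shared columns", length(object@shared@columns)))
  for (lab in names(object@cladeSpecific))
    cat(sprintf(" + %d %s-specific", length(object@cladeSpecific[[lab]]@columns),
                lab))
  cat("\n")
})

setMethod("show", "DecomposedAlignment", function(object) {
  cat(sprintf("DecomposedAlignment (%s mode): %d taxa x %d columns\n",
              object@mode, nTaxa(object@alignment), nColumns(object@alignment)))
  cat("  partitions:",
      paste(unique(object@provenance$partition), collapse = ", "), "\n")
})

setMethod("show", "CharSiteCall", function(object) {
  cat(sprintf("CharSiteCall: column %d, ingroup %s -> %s",
              object@column, object@ingroup, object@classification))
  if (object@classification != "none") {
    cat(sprintf(" [%s, ingroup %d%%, %s%s]", object@definingClass,
                roundHalfUp(100 * object@ingroupShare), object@radicality,
                if (object@weak) ", weak" else ""))
  }
  cat("\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': %s taxa, %d columns, %d planted sites, seed %d\n",
              object@preset,
              paste(object@groupSizes, collapse = "+"),
              object@nColumns, nrow(object@plantedSites), object@seed))
})
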