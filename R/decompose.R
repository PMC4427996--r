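#' Build a mutually exclusive partition of alignment columns
#'
#' Given a mask of globally well-aligned columns and raw clade-specific
#' masks (columns well aligned within each clade's sub-alignment), enforces
#' the exclusivity that makes the decomposition well defined: the shared
#' mask is kept as-is, and each clade mask loses any column already in the
#' shared mask or claimed by an earlier clade (first clade in declared order
#' wins a tie). Removals are recorded per clade in the plan.
#'
#' @param shared a [SiteMask] (may be empty) of globally well-aligned sites.
#' @param cladeMasks named list of [SiteMask] (or integer coordinate
#'   vectors), in the clade order that fixes both tie-breaking and the
#'   concatenation order of [decomposeAlignment()].
#' @param cladeMembership named list of taxon-id vectors, one per clade;
#'   membership sets must be disjoint.
#' @return A [PartitionPlan].
#' @examples
#' plan <- exclusivePartition(siteMask(c(1, 2), "shared"),
#'                            list(A = c(2, 3), B = c(3, 4)),
#'                            list(A = c("a1"), B = c("b1")))
#' maskColumns(plan@cladeSpecific$A)  # 3: column 2 was shared
#' @export
exclusivePartition <- function(shared, cladeMasks, cladeMembership) {
  if (!is(shared, "SiteMask")) shared <- siteMask(shared, "shared")
  if (is.null(names(cladeMasks)) || any(!nzchar(names(cladeMasks))))
    stopf("cladeMasks must be a named list")
  if (!setequal(names(cladeMasks), names(cladeMembership)))
    stopf("cladeMasks and cladeMembership must use the same clade labels")
  memb <- unlist(cladeMembership, use.names = FALSE)
  if (anyDuplicated(memb))
    stopf("overlapping clade membership: %s",
          paste(unique(memb[duplicated(memb)]), collapse = ", "))
  claimed <- shared@columns
  specific <- list()
  removed <- list()
  for (lab in names(cladeMasks)) {
    raw <- cladeMasks[[lab]]
    raw_cols <- if (is(raw, "SiteMask")) raw@columns else sort(unique(as.integer(raw)))
    drop <- intersect(raw_cols, claimed)
    keep <- setdiff(raw_cols, claimed)
    specific[[lab]] <- new("SiteMask", columns = as.integer(keep), label = lab)
    removed[[lab]] <- as.integer(drop)
    claimed <- c(claimed, keep)
  }
  new("PartitionPlan", shared = shared, cladeSpecific = specific,
      cladeMembership = cladeMembership[names(cladeMasks)], removed = removed)
}

#' Concatenate a partition plan into a composite (decomposed) alignment
#'
#' Builds the composite alignment: the shared columns first (ascending
#' original coordinate), then each clade's specific columns in the plan's
#' declared clade order, again ascending. All taxa are retained. In
#' \code{"retain"} mode residues are copied verbatim; in
#' \code{"gap-nonfocal"} mode every taxon outside a clade is gapped
#' (\code{"-"}) at that clade's specific columns, since those columns are by
#' construction unreliable outside the clade. Per-column provenance maps
#' each composite column to its partition and original coordinate.
#'
#' @param alignment the master [AaAlignment].
#' @param plan a [PartitionPlan] whose coordinates fit the alignment and
#'   whose clade members are alignment taxa.
#' @param mode \code{"retain"} (default) or \code{"gap-nonfocal"}.
#' @return A [DecomposedAlignment].
#' @export
decomposeAlignment <- function(alignment, plan, mode = c("retain", "gap-nonfocal")) {
  mode <- match.arg(mode)
  validObject(plan)
  nc <- nColumns(alignment)
  all_cols <- c(plan@shared@columns,
                unlist(lapply(plan@cladeSpecific, function(m) m@columns),
                       use.names = FALSE))
  if (length(all_cols) == 0L)
    stopf("partition plan selects no columns")
  if (max(all_cols) > nc)
    stopf("plan coordinate %d exceeds alignment width %d", max(all_cols), nc)
  unknown <- setdiff(unlist(plan@cladeMembership, use.names = FALSE),
                     taxonIds(alignment))
  if (length(unknown))
    stopf("clade members not in alignment: %s", paste(unknown, collapse = ", "))

  partitions <- c(rep(plan@shared@label, length(plan@shared@columns)),
                  rep(names(plan@cladeSpecific),
                      vapply(plan@cladeSpecific, function(m) length(m@columns),
                             integer(1L))))
  m <- alignment@seqs[, all_cols, drop = FALSE]
  dimnames(m) <- list(taxonIds(alignment), NULL)
  if (mode == "gap-nonfocal") {
    for (lab in names(plan@cladeSpecific)) {
      j <- which(partitions == lab)
      if (!length(j)) next
      nonfocal <- setdiff(taxonIds(alignment), plan@cladeMembership[[lab]])
      m[nonfocal, j] <- "-"
    }
  }
  prov <- data.frame(new_column = seq_along(all_cols),
                     partition = partitions,
                     original_column = as.integer(all_cols),
                     stringsAsFactors = FALSE)
  new("DecomposedAlignment", alignment = new("AaAlignment", seqs = m),
      provenance = prov, mode = mode)
}

#' Count the sites informative for one clade's internal relationship
#'
#' The columns usable for resolving the relationship between the rare and
#' common forms \emph{within} a clade are the globally shared sites plus
#' that clade's specific sites: \code{|shared| + |clade-specific|}.
#'
#' @param plan a [PartitionPlan].
#' @param clade clade label present in the plan.
#' @return Integer count.
#' @export
informativeSites <- function(plan, clade) {
  if (!clade %in% names(plan@cladeSpecific))
    stopf("unknown clade '%s' (plan has: %s)", clade,
          paste(names(plan@cladeSpecific), collapse = ", "))
  length(plan@shared@columns) + length(plan@cladeSpecific[[clade]]@columns)
}

#' Write a provenance table to TSV
#'
#' @param decomposed a [DecomposedAlignment].
#' @param path output TSV (columns \code{new_column}, \code{partition},
#'   \code{original_column}).
#' @return \code{path}, invisibly.
#' @export
writeProvenance <- function(decomposed, path) {
  utils::write.table(decomposed@provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
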