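#' Assemble a pipeline run configuration
#'
#' Bundles and validates everything one reproducible mask -> decompose ->
#' character-site run needs. Masks are optional: give either a
#' pre-computed mask file (one 1-based coordinate per line) or a score
#' table plus \code{scoreCutoff} for the shared track and for each clade;
#' with no masks at all the decomposition stage is skipped and character
#' sites are scanned on the master alignment (always scanned on master
#' coordinates either way).
#'
#' @param alignmentPath master alignment FASTA.
#' @param groupTablePath taxon grouping TSV (see [readGroupTable()]).
#' @param outDir output directory (created if absent).
#' @param sharedMaskPath,sharedScorePath optional shared-track inputs.
#' @param cladeMaskPaths,cladeScorePaths optional named lists
#'   (clade/family label -> path); clade labels must be family names of the
#'   group table, whose taxa define the clade membership.
#' @param scoreCutoff cutoff applied to score tables, default 0.5.
#' @param mode decomposition mode, \code{"retain"} or \code{"gap-nonfocal"}.
#' @param ingroups \code{"family:form"} labels to scan; default all.
#' @param shareThreshold,absenceScope,outgroupPooling,minNonGapFraction
#'   forwarded to [charSiteParams()].
#' @param seed recorded in the manifest (the standard pipeline stages are
#'   deterministic; the seed matters only if simulation steps are added).
#' @return A validated list of class \code{"runConfig"}.
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(alignmentPath, groupTablePath, outDir,
                      sharedMaskPath = NULL, sharedScorePath = NULL,
                      cladeMaskPaths = list(), cladeScorePaths = list(),
                      scoreCutoff = 0.5, mode = c("retain", "gap-nonfocal"),
                      ingroups = NULL, shareThreshold = 0.5,
                      absenceScope = "residue", outgroupPooling = "pooled",
                      minNonGapFraction = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  for (p in c(alignmentPath, groupTablePath, sharedMaskPath, sharedScorePath,
              unlist(cladeMaskPaths), unlist(cladeScorePaths)))
    if (!file.exists(p)) stopf("referenced path does not exist: %s", p)
  if (!is.null(sharedMaskPath) && !is.null(sharedScorePath))
    stopf("give sharedMaskPath or sharedScorePath, not both")
  both <- intersect(names(cladeMaskPaths), names(cladeScorePaths))
  if (length(both))
    stopf("clade(s) with both mask and scores: %s", paste(both, collapse = ", "))
  structure(list(alignmentPath = alignmentPath,
                 groupTablePath = groupTablePath, outDir = outDir,
                 sharedMaskPath = sharedMaskPath,
                 sharedScorePath = sharedScorePath,
                 cladeMaskPaths = cladeMaskPaths,
                 cladeScorePaths = cladeScorePaths,
                 scoreCutoff = scoreCutoff, mode = mode, ingroups = ingroups,
                 shareThreshold = shareThreshold, absenceScope = absenceScope,
                 outgroupPooling = outgroupPooling,
                 minNonGapFraction = minNonGapFraction,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [runConfig()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A \code{"runConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  args <- y
  for (k in c("alignmentPath", "groupTablePath", "outDir", "sharedMaskPath",
              "sharedScorePath"))
    args[[k]] <- rel(y[[k]])
  for (k in c("cladeMaskPaths", "cladeScorePaths"))
    if (!is.null(y[[k]])) args[[k]] <- lapply(y[[k]], rel)
  do.call(runConfig, args)
}

.stageMask <- function(maskPath, scorePath, cutoff, label, nCols) {
  if (!is.null(maskPath)) return(readSiteMask(maskPath, label))
  if (!is.null(scorePath))
    return(maskFromScores(readSiteScores(scorePath, nColumns = nCols),
                          cutoff, label))
  NULL
}

#' Run the full decomposition + character-site pipeline
#'
#' Executes the staged workflow on one configuration: read and validate the
#' alignment and grouping; build the shared and clade-specific masks (from
#' mask files or thresholded score tables); enforce exclusivity and build
#' the decomposed alignment with provenance (skipped, and noted in the
#' manifest, when no masks are configured); scan the master alignment for
#' character sites; and write all artifacts plus a manifest to
#' \code{outDir}:
#' \code{decomposed.fasta}, \code{provenance.tsv}, \code{charsites.tsv},
#' \code{summary.json} (per-ingroup counts and per-family mean
#' conservation) and \code{manifest.json} (config hash, package and R
#' versions, per-file MD5 checksums, skipped stages). Identical
#' configurations produce byte-identical outputs. Any stage error aborts
#' the run with the stage name attached.
#'
#' @param config a \code{"runConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return Invisibly, a list with \code{scan}, \code{summary},
#'   \code{decomposed} (or \code{NULL}), \code{plan} (or \code{NULL}) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  skipped <- character()

  aln <- stage("read_alignment", readFastaAlignment(config$alignmentPath))
  grouping <- stage("read_groups",
                    readGroupTable(config$groupTablePath, aln))
  message(sprintf("alignment: %d taxa x %d columns", nTaxa(aln), nColumns(aln)))

  shared <- stage("mask", .stageMask(config$sharedMaskPath,
                                     config$sharedScorePath,
                                     config$scoreCutoff, "shared",
                                     nColumns(aln)))
  cladeLabels <- union(names(config$cladeMaskPaths),
                       names(config$cladeScorePaths))
  cladeMasks <- stage("mask", {
    out <- list()
    for (lab in cladeLabels)
      out[[lab]] <- .stageMask(config$cladeMaskPaths[[lab]],
                               config$cladeScorePaths[[lab]],
                               config$scoreCutoff, lab, nColumns(aln))
    out
  })

  decomposed <- NULL
  plan <- NULL
  if (is.null(shared) && !length(cladeMasks)) {
    skipped <- c(skipped, "decompose")
    message("no masks configured; decomposition skipped")
  } else {
    plan <- stage("decompose", {
      a <- grouping@assignments
      membership <- lapply(stats::setNames(cladeLabels, cladeLabels),
                           function(lab) a$taxon[a$family == lab])
      bad <- cladeLabels[vapply(membership, length, 1L) == 0L]
      if (length(bad))
        stopf("clade label(s) not matching any family: %s",
              paste(bad, collapse = ", "))
      exclusivePartition(shared %||% siteMask(integer(), "shared"),
                         cladeMasks, membership)
    })
    decomposed <- stage("decompose", decomposeAlignment(aln, plan, config$mode))
    message(sprintf("decomposed alignment: %d columns (%s)",
                    nColumns(decomposed@alignment),
                    paste(sprintf("%s=%d",
                                  c("shared", names(plan@cladeSpecific)),
                                  c(length(plan@shared@columns),
                                    vapply(plan@cladeSpecific,
                                           function(m) length(m@columns), 1L))),
                          collapse = ", ")))
    writeAlignment(decomposed@alignment,
                   file.path(config$outDir, "decomposed.fasta"))
    writeProvenance(decomposed, file.path(config$outDir, "provenance.tsv"))
    files <- c(files, "decomposed.fasta", "provenance.tsv")
  }

  params <- charSiteParams(config$shareThreshold, config$absenceScope,
                           config$outgroupPooling, config$minNonGapFraction)
  ingroups <- config$ingroups %||% groupLabels(grouping)
  scan <- stage("charsites",
                scanCharSites(aln, grouping, params = params,
                              ingroups = ingroups))
  summary <- summarizeCalls(scan)
  message(sprintf("character sites called: %d (%s)", nrow(scan$calls),
                  paste(sprintf("%s: %d symplesiomorphies",
                                summary$counts$ingroup,
                                summary$counts$symplesiomorphies),
                        collapse = "; ")))
  writeCharSiteReport(scan, file.path(config$outDir, "charsites.tsv"))
  files <- c(files, "charsites.tsv")

  summaryJson <- list(
    counts = summary$counts,
    familyMeanConservation = as.list(summary$familyMeans),
    nCalls = nrow(scan$calls),
    decomposedColumns = if (is.null(decomposed)) NULL else
      nColumns(decomposed@alignment),
    informativeSites = if (is.null(plan)) NULL else
      as.list(stats::setNames(
        vapply(names(plan@cladeSpecific), informativeSites, 1L, plan = plan),
        names(plan@cladeSpecific))))
  jsonlite::write_json(summaryJson, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  files <- c(files, "summary.json")

  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  cfgFile <- tempfile()
  writeLines(cfgJson, cfgFile)
  manifest <- list(
    configHash = unname(tools::md5sum(cfgFile)),
    package = "ParalogSites",
    packageVersion = as.character(utils::packageVersion("ParalogSites")),
    rVersion = as.character(getRversion()),
    skippedStages = as.list(skipped),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(config$outDir, f))))
    }))
  unlink(cfgFile)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(scan = scan, summary = summary, decomposed = decomposed,
                 plan = plan, manifest = manifest))
}
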