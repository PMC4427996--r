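#' @import methods
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Order follows the conventional alphabetical-by-three-letter-code listing.
#' The alignment alphabet additionally admits \code{"-"} (gap) and \code{"X"}
#' (unknown residue, treated as missing for residue counts but as coverage
#' for gap accounting).
#'
#' @export
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

ALN_ALPHABET <- c(AA_RESIDUES, "-", "X")

#' AaAlignment: a validated protein multiple sequence alignment
#'
#' A thin matrix-backed container for an amino-acid multiple sequence
#' alignment: one row per taxon, one column per alignment site, every cell a
#' single upper-case character from the 20 amino acids plus \code{"-"} and
#' \code{"X"}. Row names are the taxon identifiers and must be unique and
#' non-empty. All user-facing column coordinates are 1-based.
#'
#' @slot seqs character matrix (taxa x columns) with unique row names.
#'
#' @seealso [AaAlignment()], [readFastaAlignment()], [writeAlignment()]
#' @export
setClass("AaAlignment", representation(seqs = "matrix"))

setValidity("AaAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("'seqs' must be a character matrix")
  if (nrow(m) < 1L) return("alignment must contain at least one taxon")
  if (ncol(m) < 1L) return("alignment must contain at least one column")
  ids <- rownames(m)
  if (is.null(ids) || any(!nzchar(ids)))
    return("taxon identifiers must be non-empty")
  if (anyDuplicated(ids))
    return(sprintf("duplicate taxon identifiers: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- which(!(m %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    return(sprintf(
      "illegal character '%s' at taxon '%s', column %d (alphabet: 20 amino acids, '-', 'X')",
      m[bad[1L]], ids[i], j))
  }
  TRUE
})

#' TaxonGrouping: taxon-to-(family, form) assignments
#'
#' Assigns each taxon to a family (e.g. \code{"SerRS"}) and a form
#' (\code{"rare"} or \code{"common"}); taxa playing no role (distant
#' outgroups used only for rooting, etc.) go into the \code{excluded} set.
#' Within this package's character-site vocabulary, for a focal ingroup
#' (family, form), the \emph{sister group} is the other form of the same
#' family and the \emph{outgroup} is the entire other family.
#'
#' @slot assignments data.frame with columns \code{taxon}, \code{family},
#'   \code{form} (each form one of \code{"rare"}, \code{"common"}).
#' @slot excluded character vector of taxon ids outside the analysis.
#'
#' @seealso [taxonGrouping()], [readGroupTable()], [validateGrouping()]
#' @export
setClass("TaxonGrouping",
         representation(assignments = "data.frame", excluded = "character"))

setValidity("TaxonGrouping", function(object) {
  a <- object@assignments
  need <- c("taxon", "family", "form")
  if (!all(need %in% names(a)))
    return("assignments must have columns taxon, family, form")
  if (anyDuplicated(a$taxon))
    return(sprintf("taxon assigned more than once: %s",
                   paste(unique(a$taxon[duplicated(a$taxon)]), collapse = ", ")))
  if (!all(a$form %in% c("rare", "common")))
    return("form labels must be 'rare' or 'common'")
  overlap <- intersect(a$taxon, object@excluded)
  if (length(overlap))
    return(sprintf("taxa both assigned and excluded: %s",
                   paste(overlap, collapse = ", ")))
  TRUE
})

#' SiteScoreTable: per-column alignment-confidence scores
#'
#' Holds one confidence score in [0, 1] per master-alignment column, as
#' produced by an external column scorer (GUIDANCE-style output) or by the
#' built-in surrogate scorer. Columns absent from an external file are
#' imputed with score 0 and recorded in \code{imputed}.
#'
#' @slot columns integer, 1-based column coordinates (sorted, unique).
#' @slot scores numeric in [0, 1], parallel to \code{columns}.
#' @slot source either \code{"external"} or \code{"surrogate"}.
#' @slot imputed integer, coordinates whose score was imputed as 0.
#'
#' @seealso [readSiteScores()], [surrogateColumnScores()], [maskFromScores()]
#' @export
setClass("SiteScoreTable",
         representation(columns = "integer", scores = "numeric",
                        source = "character", imputed = "integer"))

setValidity("SiteScoreTable", function(object) {
  if (length(object@columns) != length(object@scores))
    return("columns and scores must have equal length")
  if (is.unsorted(object@columns, strictly = TRUE))
    return("columns must be strictly increasing")
  if (any(object@columns < 1L))
    return("column coordinates are 1-based and must be >= 1")
  if (any(object@scores < 0 | object@scores > 1))
    return("scores must lie in [0, 1]")
  if (!object@source %in% c("external", "surrogate"))
    return("source must be 'external' or 'surrogate'")
  TRUE
})

#' SiteMask: a labelled set of alignment columns
#'
#' A strictly increasing vector of 1-based master-alignment coordinates with
#' a label, e.g. the globally well-aligned sites or the sites well aligned
#' specifically within one clade's sub-alignment.
#'
#' @slot columns integer, sorted, unique, >= 1.
#' @slot label single character string.
#'
#' @seealso [siteMask()], [maskFromScores()], [exclusivePartition()]
#' @export
setClass("SiteMask", representation(columns = "integer", label = "character"))

setValidity("SiteMask", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single non-empty string")
  cols <- object@columns
  if (length(cols) && (any(cols < 1L) || is.unsorted(cols, strictly = TRUE)))
    return("columns must be strictly increasing 1-based coordinates")
  TRUE
})

#' PartitionPlan: mutually exclusive shared and clade-specific site sets
#'
#' The decomposition plan: one mask of globally well-aligned sites plus an
#' ordered list of clade-specific masks, all pairwise disjoint, together
#' with the taxon membership of each clade. Produced by
#' [exclusivePartition()], consumed by [decomposeAlignment()] and
#' [informativeSites()].
#'
#' @slot shared [SiteMask] of globally well-aligned columns.
#' @slot cladeSpecific named list of [SiteMask], in declared clade order.
#' @slot cladeMembership named list of character vectors (taxon ids).
#' @slot removed named list recording, per clade, the raw-mask columns
#'   dropped to enforce exclusivity.
#'
#' @export
setClass("PartitionPlan",
         representation(shared = "SiteMask", cladeSpecific = "list",
                        cladeMembership = "list", removed = "list"))

setValidity("PartitionPlan", function(object) {
  labs <- names(object@cladeSpecific)
  if (length(labs) && (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs))))
    return("clade labels must be unique and non-empty")
  masks <- c(list(object@shared@columns),
             lapply(object@cladeSpecific, function(m) m@columns))
  all_cols <- unlist(masks, use.names = FALSE)
  if (anyDuplicated(all_cols))
    return("shared and clade-specific masks must be pairwise disjoint")
  memb <- unlist(object@cladeMembership, use.names = FALSE)
  if (anyDuplicated(memb))
    return("clade membership sets must be disjoint")
  if (!all(names(object@cladeMembership) %in% c(labs, character())))
    return("cladeMembership names must match cladeSpecific labels")
  TRUE
})

#' DecomposedAlignment: the concatenated composite alignment with provenance
#'
#' The composite alignment built from a [PartitionPlan]: shared columns
#' first (ascending original coordinate), then each clade's specific columns
#' in declared clade order. \code{provenance} maps every new column back to
#' its partition and original master coordinate, and is a bijection onto the
#' plan's masks.
#'
#' @slot alignment [AaAlignment] over all taxa of the master alignment.
#' @slot provenance data.frame with columns \code{new_column},
#'   \code{partition}, \code{original_column}.
#' @slot mode \code{"retain"} (residues copied verbatim) or
#'   \code{"gap-nonfocal"} (non-clade taxa gapped at clade-specific columns).
#'
#' @export
setClass("DecomposedAlignment",
         representation(alignment = "AaAlignment", provenance = "data.frame",
                        mode = "character"))

setValidity("DecomposedAlignment", function(object) {
  p <- object@provenance
  if (!all(c("new_column", "partition", "original_column") %in% names(p)))
    return("provenance must have columns new_column, partition, original_column")
  if (nrow(p) != ncol(object@alignment@seqs))
    return("provenance must describe every composite column exactly once")
  if (anyDuplicated(p$new_column) || anyDuplicated(p$original_column))
    return("provenance must be a bijection (no repeated columns)")
  if (!object@mode %in% c("retain", "gap-nonfocal"))
    return("mode must be 'retain' or 'gap-nonfocal'")
  TRUE
})

#' SimilarityScheme: physiochemical residue classes
#'
#' Named, pairwise-disjoint sets of amino acids that are treated as
#' interchangeable when profiling group conservation (e.g. \code{K/R},
#' \code{D/E}). Residues not covered by any class act as singletons.
#' Merging is opportunistic: residues of a class are reported as one merged
#' class at a column only when at least two member residues are actually
#' present in the group.
#'
#' @slot classes named list of character vectors over the 20 amino acids.
#'
#' @seealso [similarityScheme()], [defaultSimilarityScheme()]
#' @export
setClass("SimilarityScheme", representation(classes = "list"))

setValidity("SimilarityScheme", function(object) {
  res <- unlist(object@classes, use.names = FALSE)
  if (!all(res %in% AA_RESIDUES))
    return(sprintf("unknown residues in scheme: %s",
                   paste(setdiff(res, AA_RESIDUES), collapse = ", ")))
  if (anyDuplicated(res))
    return("similarity classes must be pairwise disjoint")
  if (any(lengths(object@classes) < 2L))
    return("each similarity class needs at least two residues")
  TRUE
})

#' CharSiteParams: tuning knobs for the relaxed character-site definition
#'
#' @slot shareThreshold strict lower bound on the within-group share of the
#'   defining residue class; the canonical relaxed definition uses 0.5
#'   (">50%").
#' @slot absenceScope \code{"residue"}: the defining residues carried by the
#'   ingroup must be absent from every sister-group taxon;
#'   \code{"class"}: the whole similarity class must be absent.
#' @slot outgroupPooling \code{"pooled"}: outgroup share computed over both
#'   outgroup forms pooled (taxon-weighted); \code{"per-form-majority"}:
#'   the share must clear the threshold within the larger outgroup form.
#' @slot minNonGapFraction a group whose non-gap coverage at a column falls
#'   below this fraction is ineligible there (call becomes "none").
#'
#' @seealso [charSiteParams()], [evaluateSite()], [scanCharSites()]
#' @export
setClass("CharSiteParams",
         representation(shareThreshold = "numeric", absenceScope = "character",
                        outgroupPooling = "character",
                        minNonGapFraction = "numeric"))

setValidity("CharSiteParams", function(object) {
  if (object@shareThreshold <= 0 || object@shareThreshold >= 1)
    return("shareThreshold must lie in (0, 1)")
  if (object@minNonGapFraction <= 0 || object@minNonGapFraction > 1)
    return("minNonGapFraction must lie in (0, 1]")
  if (!object@absenceScope %in% c("residue", "class"))
    return("absenceScope must be 'residue' or 'class'")
  if (!object@outgroupPooling %in% c("pooled", "per-form-majority"))
    return("outgroupPooling must be 'pooled' or 'per-form-majority'")
  TRUE
})

#' GroupProfile: one group's residue profile at one column
#'
#' Residue counts for one taxon group at one alignment column, aggregated to
#' similarity classes where at least two class members are present, with the
#' dominant class, its share of non-gap non-X residues, and a display string
#' such as \code{"R/K(80)"} (or \code{"not conserved"} when no class exceeds
#' 50\%, \code{"-"} when the group is ineligible).
#'
#' @export
setClass("GroupProfile",
         representation(label = "character", nTaxa = "integer",
                        nonGap = "integer", nEffective = "integer",
                        residueCounts = "integer", classCounts = "integer",
                        classResidues = "list",
                        dominantClass = "character", dominantShare = "numeric",
                        eligible = "logical"))

#' CharSiteCall: the classification of one column for one ingroup
#'
#' Result of [evaluateSite()]: the column's classification
#' (\code{"symplesiomorphy"}, \code{"synapomorphy"} or \code{"none"}), the
#' defining residue class and its ingroup/outgroup shares, the four group
#' profiles, a radicality verdict for the ingroup-vs-sister difference, and
#' the weak flag (set when the defining class fails the outgroup threshold
#' but is still the outgroup's plurality class; weak calls are excluded from
#' headline counts).
#'
#' @export
setClass("CharSiteCall",
         representation(column = "integer", ingroup = "character",
                        classification = "character",
                        definingClass = "character",
                        definingResidues = "character",
                        ingroupShare = "numeric", outgroupShare = "numeric",
                        profiles = "list", radicality = "character",
                        weak = "logical", reason = "character"))

setValidity("CharSiteCall", function(object) {
  if (!object@classification %in% c("symplesiomorphy", "synapomorphy", "none"))
    return("classification must be symplesiomorphy, synapomorphy or none")
  TRUE
})

#' ScenarioConfig: parameters of the synthetic paralog-pair generator
#'
#' Describes one simulation scenario over the four groups commonA, rareA,
#' commonB, rareB (families A and B standing for a paralog pair such as
#' SerRS/ThrRS). Under the \code{"deep_divergence"} preset the four groups
#' form the rooted topology ((commonA, rareA), (commonB, rareB)); under the
#' \code{"lba"} preset rareA instead attaches on a long stem inside the
#' commonA clade, mimicking a long-branch artifact candidate.
#'
#' @slot preset \code{"deep_divergence"} or \code{"lba"}.
#' @slot groupSizes named integer (commonA, rareA, commonB, rareB), each >= 2.
#' @slot stemLengths named numeric, expected substitutions/site on each
#'   group's stem branch.
#' @slot familyStem numeric, branch length from the root to each family's
#'   ancestor.
#' @slot withinLength numeric, terminal branch length inside each group.
#' @slot nColumns integer number of alignment columns.
#' @slot slowSiteFraction fraction of columns in the slow site class.
#' @slot slowRateMultiplier rate multiplier of the slow class (0 = invariant).
#' @slot plantedSites data.frame(column, classification, ingroup,
#'   definingResidue, backgroundResidue); planted columns are placed in the
#'   slow class so their truth labels stay valid.
#' @slot seed integer RNG seed.
#'
#' @seealso [scenarioConfig()], [simulateAlignment()], [scenarioExperiment()]
#' @export
setClass("ScenarioConfig",
         representation(preset = "character", groupSizes = "integer",
                        stemLengths = "numeric", familyStem = "numeric",
                        withinLength = "numeric", nColumns = "integer",
                        slowSiteFraction = "numeric",
                        slowRateMultiplier = "numeric",
                        plantedSites = "data.frame", seed = "integer"))

SIM_GROUPS <- c("commonA", "rareA", "commonB", "rareB")

setValidity("ScenarioConfig", function(object) {
  if (!object@preset %in% c("deep_divergence", "lba"))
    return("preset must be 'deep_divergence' or 'lba'")
  if (!identical(names(object@groupSizes), SIM_GROUPS) ||
      !identical(names(object@stemLengths), SIM_GROUPS))
    return("groupSizes and stemLengths must be named commonA, rareA, commonB, rareB")
  if (any(object@groupSizes < 2L))
    return("each group needs at least 2 taxa")
  if (any(object@stemLengths < 0) || object@familyStem < 0 ||
      object@withinLength < 0)
    return("branch lengths must be >= 0")
  if (object@nColumns < 1L)
    return("nColumns must be positive")
  if (object@slowSiteFraction < 0 || object@slowSiteFraction > 1)
    return("slowSiteFraction must lie in [0, 1]")
  if (object@slowRateMultiplier < 0)
    return("slowRateMultiplier must be >= 0")
  ps <- object@plantedSites
  if (nrow(ps)) {
    need <- c("column", "classification", "ingroup",
              "definingResidue", "backgroundResidue")
    if (!all(need %in% names(ps)))
      return(sprintf("plantedSites needs columns: %s", paste(need, collapse = ", ")))
    if (anyDuplicated(ps$column))
      return("planted columns must be unique")
    if (any(ps$column < 1L | ps$column > object@nColumns))
      return("planted columns out of range")
    if (!all(ps$classification %in% c("symplesiomorphy", "synapomorphy")))
      return("planted classification must be symplesiomorphy or synapomorphy")
    if (!all(ps$ingroup %in% SIM_GROUPS))
      return("planted ingroup must be one of commonA, rareA, commonB, rareB")
    if (!all(c(ps$definingResidue, ps$backgroundResidue) %in% AA_RESIDUES))
      return("planted residues must be amino-acid one-letter codes")
    if (any(ps$definingResidue == ps$backgroundResidue))
      return("defining and background residues must differ")
  }
  TRUE
})
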