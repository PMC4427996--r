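#' Construct a simulation scenario
#'
#' Describes a synthetic paralog-pair alignment over four groups (commonA,
#' rareA, commonB, rareB). The \code{"deep_divergence"} preset realises the
#' rooted topology ((commonA, rareA), (commonB, rareB)) — both rare forms
#' genuinely predate their family's crown group — while the \code{"lba"}
#' preset nests rareA inside the commonA clade on a long stem, the
#' long-branch-attraction alternative in which rareA's deep placement in an
#' inferred tree would be artifactual. Planted character-site columns carry
#' a known truth label and are placed in the slow site class so the label
#' survives simulation.
#'
#' @param preset \code{"deep_divergence"} or \code{"lba"}.
#' @param groupSizes named integer vector (commonA, rareA, commonB, rareB),
#'   each >= 2; default 8 taxa per group.
#' @param stemLengths named numeric vector of expected substitutions/site on
#'   each group's stem branch; default 1 each.
#' @param familyStem root-to-family-ancestor branch length, default 0.5.
#' @param withinLength terminal branch length inside each group, default 0.05.
#' @param nColumns alignment width, default 200.
#' @param slowSiteFraction fraction of columns in the slow class, default 0.3.
#' @param slowRateMultiplier rate multiplier of the slow class, default 0
#'   (invariant).
#' @param plantedSites data.frame with columns \code{column},
#'   \code{classification} (\code{"symplesiomorphy"} or
#'   \code{"synapomorphy"}), \code{ingroup} (one of the four group names),
#'   \code{definingResidue}, \code{backgroundResidue}.
#' @param seed RNG seed.
#' @return A [ScenarioConfig].
#' @seealso [simulateAlignment()], [buildScenarioTree()], [scenarioExperiment()]
#' @export
scenarioConfig <- function(preset = c("deep_divergence", "lba"),
                           groupSizes = c(commonA = 8L, rareA = 8L,
                                          commonB = 8L, rareB = 8L),
                           stemLengths = c(commonA = 1, rareA = 1,
                                           commonB = 1, rareB = 1),
                           familyStem = 0.5, withinLength = 0.05,
                           nColumns = 200L, slowSiteFraction = 0.3,
                           slowRateMultiplier = 0,
                           plantedSites = emptyPlantedSites(), seed = 1L) {
  preset <- match.arg(preset)
  new("ScenarioConfig", preset = preset,
      groupSizes = stats::setNames(as.integer(groupSizes[SIM_GROUPS]), SIM_GROUPS),
      stemLengths = stats::setNames(as.numeric(stemLengths[SIM_GROUPS]), SIM_GROUPS),
      familyStem = as.numeric(familyStem),
      withinLength = as.numeric(withinLength),
      nColumns = as.integer(nColumns),
      slowSiteFraction = as.numeric(slowSiteFraction),
      slowRateMultiplier = as.numeric(slowRateMultiplier),
      plantedSites = plantedSites, seed = as.integer(seed))
}

#' @rdname scenarioConfig
#' @export
emptyPlantedSites <- function() {
  data.frame(column = integer(), classification = character(),
             ingroup = character(), definingResidue = character(),
             backgroundResidue = character(), stringsAsFactors = FALSE)
}

#' Helper for building a planted-sites table
#'
#' @param column,classification,ingroup,definingResidue,backgroundResidue
#'   parallel vectors; see [scenarioConfig()].
#' @return data.frame suitable for \code{plantedSites}.
#' @export
plantedSites <- function(column, classification, ingroup, definingResidue,
                         backgroundResidue) {
  data.frame(column = as.integer(column),
             classification = as.character(classification),
             ingroup = as.character(ingroup),
             definingResidue = as.character(definingResidue),
             backgroundResidue = as.character(backgroundResidue),
             stringsAsFactors = FALSE)
}

# taxon ids per group, e.g. commonA_01 ... commonA_08
.simTaxa <- function(config) {
  lapply(stats::setNames(SIM_GROUPS, SIM_GROUPS), function(g) {
    sprintf("%s_%02d", g, seq_len(config@groupSizes[[g]]))
  })
}

#' Build the scenario's phylogeny
#'
#' Returns the scenario tree as an \pkg{ape} \code{phylo} object. Each
#' group is a star clade of terminal branches (\code{withinLength}) under a
#' labelled ancestral node; group stems carry the configured stem lengths.
#' Under \code{"deep_divergence"} the root splits family A from family B;
#' under \code{"lba"} the rareA clade attaches as a child of the commonA
#' ancestor, so rareA's most recent common ancestor lies inside the commonA
#' clade. Internal node labels name each group's ancestor, which is how
#' [simulateAlignment()] locates stem branches for planted overrides.
#'
#' @param config a [ScenarioConfig].
#' @return An \code{ape::phylo} with node labels \code{anc_commonA} etc.
#' @export
buildScenarioTree <- function(config) {
  validObject(config)
  taxa <- .simTaxa(config)
  clade <- function(g) {
    tips <- paste0(taxa[[g]], ":", config@withinLength, collapse = ",")
    sprintf("(%s)anc_%s", tips, g)
  }
  sl <- config@stemLengths
  if (config@preset == "deep_divergence") {
    nwk <- sprintf("((%s:%g,%s:%g)anc_famA:%g,(%s:%g,%s:%g)anc_famB:%g)root;",
                   clade("commonA"), sl[["commonA"]],
                   clade("rareA"), sl[["rareA"]], config@familyStem,
                   clade("commonB"), sl[["commonB"]],
                   clade("rareB"), sl[["rareB"]], config@familyStem)
  } else {
    # rareA's clade is a child of the commonA ancestor, on its own long stem
    tipsCA <- paste0(taxa[["commonA"]], ":", config@withinLength, collapse = ",")
    nwk <- sprintf("((%s,%s:%g)anc_commonA:%g,(%s:%g,%s:%g)anc_famB:%g)root;",
                   tipsCA, clade("rareA"), sl[["rareA"]],
                   config@familyStem + sl[["commonA"]],
                   clade("commonB"), sl[["commonB"]],
                   clade("rareB"), sl[["rareB"]], config@familyStem)
  }
  ape::read.tree(text = nwk)
}

# which stem (edge into which labelled ancestor node) must be overridden to
# realise a planted site; NULL label means the override is impossible
.plantOverrideNode <- function(preset, classification, ingroup) {
  sisterOf <- c(commonA = "rareA", rareA = "commonA",
                commonB = "rareB", rareB = "commonB")
  if (classification == "synapomorphy") {
    if (preset == "lba" && ingroup == "commonA")
      stopf(paste0("cannot plant a synapomorphy for commonA under the lba ",
                   "preset: rareA is nested inside commonA and would inherit ",
                   "the defining residue"))
    return(paste0("anc_", ingroup))
  }
  if (preset == "lba" && ingroup == "rareA")
    stopf(paste0("cannot plant a symplesiomorphy for rareA under the lba ",
                 "preset: rareA is nested inside commonA, so no bipartition ",
                 "separates commonA from rareA + family B"))
  paste0("anc_", sisterOf[[ingroup]])
}

#' Simulate a paralog-pair alignment with known character-site truth
#'
#' Evolves each column independently along the scenario tree under a
#' uniform-exchange amino-acid substitution process: on a branch of length
#' t, a site of relative rate r receives Poisson(t * r) substitutions, each
#' replacing the current residue by one of the other 19 uniformly. A
#' deliberate simplification of empirical exchange matrices (LG etc.): the
#' character-site argument only needs slow sites and topology, and the
#' uniform model keeps expectations calculable in closed form. Root states
#' are uniform over the 20 residues. Columns are split into a slow class
#' (fraction \code{slowSiteFraction}, rate \code{slowRateMultiplier}) and a
#' background class (rate 1); planted columns always join the slow class.
#'
#' A planted symplesiomorphy for ingroup g starts the whole tree at the
#' defining residue and forces the sister group's stem to switch to the
#' background residue, so g and the opposite family share the ancestral
#' state while the sister group carries the derived one. A planted
#' synapomorphy starts at the background residue and forces g's own stem to
#' the defining residue. Below the forced branch the site evolves at the
#' slow rate as usual.
#'
#' @param config a [ScenarioConfig]; \code{config@seed} makes the run
#'   reproducible.
#' @return A list: \code{alignment} ([AaAlignment]), \code{truth}
#'   (data.frame \code{column}, \code{classification}, \code{ingroup},
#'   \code{definingResidue}), \code{grouping} ([TaxonGrouping] with
#'   families \code{"A"}/\code{"B"}), \code{tree} (\code{phylo}),
#'   \code{siteRates} (numeric per column).
#' @export
simulateAlignment <- function(config) {
  validObject(config)
  set.seed(config@seed)
  tree <- buildScenarioTree(config)
  nc <- config@nColumns
  ps <- config@plantedSites

  # validate plant feasibility up front (errors even before simulating)
  overrideNode <- character(nrow(ps))
  for (i in seq_len(nrow(ps)))
    overrideNode[i] <- .plantOverrideNode(config@preset, ps$classification[i],
                                          ps$ingroup[i])

  # site rate classes: planted columns are always slow
  nSlow <- min(nc, max(round(config@slowSiteFraction * nc), nrow(ps)))
  slowPool <- setdiff(seq_len(nc), ps$column)
  slowExtra <- if (nSlow > nrow(ps))
    sample(slowPool, nSlow - nrow(ps)) else integer()
  slowCols <- sort(c(ps$column, slowExtra))
  rates <- rep(1, nc)
  rates[slowCols] <- config@slowRateMultiplier

  # root states
  root <- sample.int(20L, nc, replace = TRUE)
  resIndex <- stats::setNames(seq_len(20L), AA_RESIDUES)
  for (i in seq_len(nrow(ps))) {
    start <- if (ps$classification[i] == "symplesiomorphy")
      ps$definingResidue[i] else ps$backgroundResidue[i]
    root[ps$column[i]] <- resIndex[[start]]
  }
  forcedState <- integer(nrow(ps))
  for (i in seq_len(nrow(ps))) {
    forcedState[i] <- if (ps$classification[i] == "symplesiomorphy")
      resIndex[[ps$backgroundResidue[i]]] else resIndex[[ps$definingResidue[i]]]
  }

  # preorder traversal over edges
  nTips <- length(tree$tip.label)
  nodeState <- matrix(0L, nrow = nTips + tree$Nnode, ncol = nc)
  rootNode <- nTips + 1L
  nodeState[rootNode, ] <- root
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  edgeLen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  nodeLabelOf <- function(node) {
    if (node > nTips) tree$node.label[node - nTips] else tree$tip.label[node]
  }
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    state <- nodeState[parent, ]
    len <- edgeLen[e]
    nsub <- stats::rpois(nc, len * rates)
    for (j in which(nsub > 0L)) {
      s <- state[j]
      for (k in seq_len(nsub[j])) {
        pick <- sample.int(19L, 1L)
        s <- if (pick >= s) pick + 1L else pick
      }
      state[j] <- s
    }
    # planted overrides pin the state at the end of the designated stem
    lab <- nodeLabelOf(child)
    hit <- which(overrideNode == lab)
    if (length(hit)) state[ps$column[hit]] <- forcedState[hit]
    nodeState[child, ] <- state
  }

  m <- matrix(AA_RESIDUES[nodeState[seq_len(nTips), , drop = FALSE]],
              nrow = nTips, dimnames = list(tree$tip.label, NULL))
  taxa <- .simTaxa(config)
  grouping <- taxonGrouping(
    taxon = unlist(taxa, use.names = FALSE),
    family = rep(c("A", "A", "B", "B"), lengths(taxa)[SIM_GROUPS]),
    form = rep(c("common", "rare", "common", "rare"), lengths(taxa)[SIM_GROUPS]))
  truth <- data.frame(column = ps$column, classification = ps$classification,
                      ingroup = ps$ingroup,
                      definingResidue = ps$definingResidue,
                      stringsAsFactors = FALSE)
  list(alignment = AaAlignment(m[unlist(taxa, use.names = FALSE), , drop = FALSE]),
       truth = truth, grouping = grouping, tree = tree, siteRates = rates)
}

# map simulator group names to grouping labels
simGroupLabel <- c(commonA = "A:common", rareA = "A:rare",
                   commonB = "B:common", rareB = "B:rare")

#' Replicated simulate-then-scan experiment
#'
#' Runs \code{nReplicates} independent simulations of a scenario (replicate
#' i uses seed \code{config@seed + i}), scans each simulated alignment with
#' [scanCharSites()], and summarises the per-ingroup symplesiomorphy counts
#' (weak calls excluded). This operationalises the stem-length argument:
#' under genuine deep divergence the expected number of symplesiomorphies
#' for an ingroup scales with the length of its \emph{sister} group's stem
#' (the branch on which the defining substitution must occur), whereas a
#' nested (LBA) rare group can only accumulate apparent symplesiomorphies
#' through convergent substitutions.
#'
#' @param config a [ScenarioConfig].
#' @param nReplicates number of replicates, >= 1.
#' @param ingroups grouping labels to scan; default \code{c("A:rare",
#'   "A:common")}.
#' @param scheme,params passed to [scanCharSites()].
#' @return A list: \code{perReplicate} (data.frame replicate x ingroup
#'   symplesiomorphy count), \code{summary} (data.frame of per-ingroup mean
#'   counts), \code{ratio} (mean count of the first ingroup over the
#'   second, \code{NA} when undefined).
#' @export
scenarioExperiment <- function(config, nReplicates,
                               ingroups = c("A:rare", "A:common"),
                               scheme = defaultSimilarityScheme(),
                               params = charSiteParams()) {
  stopifnot(nReplicates >= 1L)
  rows <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    cfg <- config
    cfg@seed <- config@seed + i
    sim <- simulateAlignment(cfg)
    scan <- scanCharSites(sim$alignment, sim$grouping, scheme, params,
                          ingroups = ingroups)
    cnt <- stats::setNames(scan$counts$symplesiomorphies, scan$counts$ingroup)
    rows[[i]] <- data.frame(replicate = i, ingroup = ingroups,
                            symplesiomorphies = unname(cnt[ingroups]),
                            stringsAsFactors = FALSE)
  }
  perReplicate <- do.call(rbind, rows)
  means <- vapply(ingroups, function(ing) {
    mean(perReplicate$symplesiomorphies[perReplicate$ingroup == ing])
  }, numeric(1L))
  ratio <- if (length(ingroups) >= 2L && means[2L] > 0)
    means[1L] / means[2L] else NA_real_
  list(perReplicate = perReplicate,
       summary = data.frame(ingroup = ingroups, meanSymplesiomorphies = unname(means),
                            stringsAsFactors = FALSE),
       ratio = ratio)
}

#' Write a truth table to TSV
#'
#' @param truth the \code{truth} data.frame of [simulateAlignment()].
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
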