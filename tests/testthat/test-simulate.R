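simLabel <- c(commonA = "A:common", rareA = "A:rare",
              commonB = "B:common", rareB = "B:rare")

# fraction of truth rows recovered by a scan
recoveredFraction <- function(sim, scan) {
  truth <- sim$truth
  if (!nrow(truth)) return(NA_real_)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    any(scan$calls$column == truth$column[i] &
          scan$calls$ingroup == simLabel[[truth$ingroup[i]]] &
          scan$calls$classification == truth$classification[i] &
          !scan$calls$weak)
  }, logical(1L))
  mean(hits)
}

test_that("scenario trees realise the deep-divergence and LBA topologies", {
  cfg <- scenarioConfig("deep_divergence", seed = 3L)
  tr <- buildScenarioTree(cfg)
  taxa <- split(tr$tip.label, sub("_[0-9]+$", "", tr$tip.label))
  for (g in names(taxa))
    expect_true(ape::is.monophyletic(tr, taxa[[g]]))
  # the A/B split is the root: families are reciprocally monophyletic
  expect_true(ape::is.monophyletic(tr, unlist(taxa[c("commonA", "rareA")])))
  expect_true(ape::is.monophyletic(tr, unlist(taxa[c("commonB", "rareB")])))

  lba <- buildScenarioTree(scenarioConfig("lba", seed = 3L))
  ltaxa <- split(lba$tip.label, sub("_[0-9]+$", "", lba$tip.label))
  # rareA's ancestor lies inside the commonA clade
  expect_identical(ape::getMRCA(lba, unlist(ltaxa[c("commonA", "rareA")])),
                   ape::getMRCA(lba, ltaxa$commonA))
  expect_false(ape::is.monophyletic(lba, ltaxa$commonA))
  expect_true(ape::is.monophyletic(lba, ltaxa$rareA))

  # newick round trip preserves topology and branch lengths
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
})

test_that("simulation is seed-deterministic and invariant at rate zero", {
  ps <- plantedSites(c(4, 9), c("symplesiomorphy", "symplesiomorphy"),
                     c("rareA", "commonA"), c("P", "H"), c("G", "E"))
  cfg <- scenarioConfig("deep_divergence",
                        groupSizes = c(commonA = 3L, rareA = 3L,
                                       commonB = 3L, rareB = 3L),
                        nColumns = 20L, slowSiteFraction = 1,
                        slowRateMultiplier = 0, plantedSites = ps, seed = 42L)
  sim1 <- simulateAlignment(cfg)
  sim2 <- simulateAlignment(cfg)
  expect_identical(alignmentMatrix(sim1$alignment), alignmentMatrix(sim2$alignment))

  m <- alignmentMatrix(sim1$alignment)
  # every non-planted column is uniform: the root state propagated unchanged
  for (j in setdiff(seq_len(ncol(m)), ps$column))
    expect_identical(length(unique(m[, j])), 1L)
  # planted symplesiomorphy geometry: ingroup+outgroup defining, sister background
  expect_true(all(m[grep("rareA", rownames(m)), 4] == "P"))
  expect_true(all(m[grep("commonA", rownames(m)), 4] == "G"))
  expect_true(all(m[grep("B", rownames(m)), 4] == "P"))

  scan <- scanCharSites(sim1$alignment, sim1$grouping,
                        ingroups = c("A:rare", "A:common"))
  expect_equal(recoveredFraction(sim1, scan), 1)
  # and nothing is called anywhere else
  expect_true(all(scan$calls$column %in% ps$column))

  # one-replicate experiment at rate zero reports exactly the planted counts
  ex <- scenarioExperiment(cfg, 1L)
  expect_identical(ex$perReplicate$symplesiomorphies, c(1L, 1L))
})

test_that("substitution process matches the uniform-exchange closed form", {
  # under uniform exchange at rate r for time t,
  # P(same residue) = 1/20 + (19/20) exp(-(20/19) r t)
  cfg <- scenarioConfig("deep_divergence", nColumns = 3000L,
                        slowSiteFraction = 0, seed = 5L)
  sim <- simulateAlignment(cfg)
  m <- alignmentMatrix(sim$alignment)
  pSame <- function(t) 1 / 20 + (19 / 20) * exp(-(20 / 19) * t)
  checkPair <- function(a, b, t) {
    obs <- mean(m[a, ] == m[b, ])
    p <- pSame(t)
    tol <- 4 * sqrt(p * (1 - p) / ncol(m))
    expect_lt(abs(obs - p), tol)
  }
  checkPair("commonA_01", "commonA_02", 2 * 0.05)       # within a group
  checkPair("commonA_01", "rareA_01", 0.05 + 1 + 1 + 0.05)  # across the A stems
  checkPair("commonA_01", "commonB_01", 0.05 + 1 + 0.5 + 0.5 + 1 + 0.05)
})

test_that("planted-site recovery degrades monotonically with the slow-site rate", {
  ps <- plantedSites(c(3, 11, 17),
                     c("symplesiomorphy", "symplesiomorphy", "synapomorphy"),
                     c("rareA", "commonA", "rareA"),
                     c("P", "H", "W"), c("G", "E", "A"))
  recovery <- vapply(c(0, 0.25, 1), function(rate) {
    fr <- vapply(1:25, function(i) {
      cfg <- scenarioConfig("deep_divergence",
                            groupSizes = c(commonA = 3L, rareA = 3L,
                                           commonB = 3L, rareB = 3L),
                            nColumns = 30L, slowSiteFraction = 0.5,
                            slowRateMultiplier = rate, plantedSites = ps,
                            seed = 1000L + i)
      sim <- simulateAlignment(cfg)
      recoveredFraction(sim, scanCharSites(sim$alignment, sim$grouping,
                                           ingroups = c("A:rare", "A:common")))
    }, numeric(1L))
    mean(fr)
  }, numeric(1L))
  expect_equal(recovery[1L], 1)
  expect_true(all(diff(recovery) <= 0))
  expect_lt(recovery[3L], recovery[1L])
})

test_that("impossible plantings under the LBA preset are rejected with an explanation", {
  bad <- scenarioConfig("lba", plantedSites = plantedSites(
    1, "symplesiomorphy", "rareA", "P", "G"))
  expect_error(simulateAlignment(bad), "nested inside commonA")
  bad2 <- scenarioConfig("lba", plantedSites = plantedSites(
    1, "synapomorphy", "commonA", "P", "G"))
  expect_error(simulateAlignment(bad2), "inherit")
  # the mirrored plantings are fine
  ok <- scenarioConfig("lba", nColumns = 10L, slowSiteFraction = 1,
                       slowRateMultiplier = 0,
                       plantedSites = plantedSites(
                         c(1, 2), c("symplesiomorphy", "synapomorphy"),
                         c("commonA", "rareA"), c("H", "W"), c("E", "A")),
                       seed = 8L)
  sim <- simulateAlignment(ok)
  scan <- scanCharSites(sim$alignment, sim$grouping,
                        ingroups = c("A:rare", "A:common"))
  expect_equal(recoveredFraction(sim, scan), 1)
})

test_that("config validation catches malformed scenarios", {
  expect_error(scenarioConfig("deep_divergence",
                              groupSizes = c(commonA = 1L, rareA = 4L,
                                             commonB = 4L, rareB = 4L)),
               "at least 2")
  expect_error(scenarioConfig("deep_divergence", plantedSites = plantedSites(
    c(5, 5), rep("synapomorphy", 2), c("rareA", "rareA"), c("P", "G"), c("G", "P"))),
    "unique")
  expect_error(scenarioConfig("deep_divergence", nColumns = 4L,
                              plantedSites = plantedSites(
                                9, "synapomorphy", "rareA", "P", "G")),
               "range")
})
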