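# Per-group residue composition (in percent) of the seven canonical
# SerRS/ThrRS character-site columns, keyed by their master-alignment site
# numbers. Group order: SerRS common, SerRS rare, ThrRS common, ThrRS rare.
# The dominant entries reproduce the published per-group conservation
# profiles (e.g. 598: G(65) / P(89) / P(86) / P(100)); the remainder of
# each group is filled with residues chosen so that no unintended class
# clears the 50% threshold and defining residues stay absent from the
# groups they must be absent from. At site 1082 the rare-ThrRS remainder is
# V (17%), so that the pooled-ThrRS V share exceeds 50% with equal group
# sizes, as it does in the real data where the common-ThrRS group is the
# larger one.
.benchmarkSites <- function() {
  list(
    "598" = list(commonSer = c(G = 65, A = 35),
                 rareSer   = c(P = 89, C = 11),
                 commonThr = c(P = 86, W = 14),
                 rareThr   = c(P = 100)),
    "758" = list(commonSer = c(R = 43, K = 37, A = 20),
                 rareSer   = c(G = 100),
                 commonThr = c(G = 98, C = 2),
                 rareThr   = c(G = 100)),
    "995" = list(commonSer = c(L = 40, M = 24, H = 36),
                 rareSer   = c(F = 100),
                 commonThr = c(F = 80, C = 20),
                 rareThr   = c(F = 64, H = 36)),
    "568" = list(commonSer = c(H = 98, Q = 2),
                 rareSer   = c(E = 56, A = 44),
                 commonThr = c(H = 98, N = 2),
                 rareThr   = c(H = 83, Q = 17)),
    "994" = list(commonSer = c(R = 88, A = 12),
                 rareSer   = c(G = 94, C = 6),
                 commonThr = c(R = 89, N = 11),
                 rareThr   = c(R = 97, Q = 3)),
    "1082" = list(commonSer = c(V = 71, A = 29),
                  rareSer   = c(E = 44, K = 22, L = 17, I = 17),
                  commonThr = c(V = 86, A = 14),
                  rareThr   = c(E = 83, V = 17)),
    "1101" = list(commonSer = c(E = 99, Q = 1),
                  rareSer   = c(A = 83, C = 17),
                  commonThr = c(E = 100),
                  rareThr   = c(E = 83, V = 17)))
}

# filler columns designed to yield no character-site call of any kind:
# uniform columns (no absence possible), sub-threshold spreads, columns
# whose dominant class is shared by every group, gap-heavy columns
# (ineligible) and X-heavy columns
.benchmarkFillers <- function() {
  same <- function(spec) list(commonSer = spec, rareSer = spec,
                              commonThr = spec, rareThr = spec)
  c(lapply(c("A", "G", "S", "L", "D"), function(r) {
      same(stats::setNames(100, r))
    }),
    list(same(c(A = 34, G = 33, N = 33)),
         same(c(H = 34, P = 33, W = 33)),
         same(c(Q = 34, C = 33, Y = 33)),
         same(c(K = 26, D = 25, F = 25, T = 24)),
         same(c(R = 40, N = 30, W = 30)),
         same(c(G = 40, E = 30, S = 30)),
         same(c(S = 80, T = 20)),
         same(c(E = 70, Q = 30)),
         same(c(M = 60, A = 40)),
         same(c(P = 90, G = 10)),
         same(c(W = 55, F = 45)),
         same(c(`-` = 60, Q = 40)),
         same(c(`-` = 60, Q = 40)),
         same(c(`-` = 55, K = 45)),
         same(c(X = 30, M = 70)),
         same(c(X = 20, H = 80))))
}

#' Build the SerRS/ThrRS character-site benchmark alignment
#'
#' Constructs, fully in code and deterministically, a four-group alignment
#' (common/rare SerRS, common/rare ThrRS) whose seven designated columns
#' realise the canonical per-group conservation profiles of the SerRS/ThrRS
#' character-site comparison — sites 598, 758, 995 (rare-SerRS
#' symplesiomorphies) and 568, 994, 1082, 1101 (common-SerRS
#' symplesiomorphies), with site 1082's rare-SerRS column split E(44)/K(22)
#' and hence "not conserved". The designated columns are embedded among 21
#' filler columns engineered to produce no call (uniform, sub-threshold,
#' shared-dominant, gap-heavy and X-heavy designs). Scanning the fixture
#' with default settings therefore yields exactly 3 rare-SerRS and 4
#' common-SerRS symplesiomorphies, with a mean defining-class conservation
#' of 92\% across the seven sites.
#'
#' @param groupSize taxa per group; must be a multiple of 100 so that the
#'   percentage profiles are realised by integer counts (default 100).
#' @return A list: \code{alignment} ([AaAlignment], \code{4 * groupSize}
#'   taxa, 28 columns), \code{grouping} ([TaxonGrouping], families
#'   \code{"SerRS"}/\code{"ThrRS"}), \code{sites} (data.frame mapping each
#'   designated alignment column to its canonical site label, expected
#'   ingroup and expected classification).
#' @examples
#' fx <- makeCharSiteBenchmark()
#' scan <- scanCharSites(fx$alignment, fx$grouping)
#' scan$counts
#' @export
makeCharSiteBenchmark <- function(groupSize = 100L) {
  groupSize <- as.integer(groupSize)
  if (groupSize < 100L || groupSize %% 100L != 0L)
    stopf(paste0("groupSize must be a positive multiple of 100 so that the ",
                 "percentage profiles are integer residue counts (got %d)"),
          groupSize)
  scale <- groupSize / 100L

  groups <- c("commonSer", "rareSer", "commonThr", "rareThr")
  sites <- .benchmarkSites()
  fillers <- .benchmarkFillers()

  # designated sites sit at every fourth column (3, 7, ..., 27) among filler
  nCols <- length(sites) + length(fillers)
  sitePos <- 4L * seq_along(sites) - 1L
  colSpecs <- vector("list", nCols)
  colLabel <- character(nCols)
  colSpecs[sitePos] <- sites
  colLabel[sitePos] <- names(sites)
  fillPos <- setdiff(seq_len(nCols), sitePos)
  colSpecs[fillPos] <- fillers
  colLabel[fillPos] <- sprintf("filler%02d", seq_along(fillPos))

  expandCol <- function(spec) {
    unlist(lapply(groups, function(g) {
      counts <- spec[[g]]
      pad <- groupSize - sum(counts) * scale
      stopifnot(pad == 0L)
      rep(names(counts), counts * scale)
    }), use.names = FALSE)
  }
  m <- vapply(colSpecs, expandCol, character(4L * groupSize))
  rownames(m) <- unlist(lapply(groups, function(g) {
    sprintf("%s_%03d", g, seq_len(groupSize))
  }), use.names = FALSE)

  grouping <- taxonGrouping(
    taxon = rownames(m),
    family = rep(c("SerRS", "SerRS", "ThrRS", "ThrRS"), each = groupSize),
    form = rep(c("common", "rare", "common", "rare"), each = groupSize))

  expected <- data.frame(
    column = sitePos,
    label = names(sites),
    expectedIngroup = c("SerRS:rare", "SerRS:rare", "SerRS:rare",
                        "SerRS:common", "SerRS:common", "SerRS:common",
                        "SerRS:common"),
    expectedClassification = "symplesiomorphy",
    stringsAsFactors = FALSE)

  list(alignment = AaAlignment(m), grouping = grouping, sites = expected)
}
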