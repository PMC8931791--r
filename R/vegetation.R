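# Biweekly wet-season vegetation dynamics: transpiration-driven growth,
# seed dispersal, water-gated establishment, and end-of-season mortality.
# Cover is tracked per grid cell and strategy type; a cell's total cover is
# a shared budget (never above 1), enforced by proportional scaling of
# competing increments.

#' Vegetation process constants
#'
#' Declared defaults for the free constants of the vegetation submodel; all
#' overridable via `scenarioConfig(vegConstants = ...)`.
#'
#' @param wue water-use efficiency: cover gained per mm transpired.
#' @param b0 background (senescence) share of the annual mortality rate.
#' @param pEst establishment probability per unit seed bank.
#' @param estMargin moisture margin (vol fraction) above the wilting point
#'   required for establishment.
#' @param quantum cover quantum for stochastic rounding of establishment.
#' @param kernelMean e-folding distance (cells) of the local shrub seed
#'   kernel.
#' @param ldRate herbivore-mediated long-distance shrub dispersal events
#'   per cell, per biweekly step and per unit type cover, at a stocking
#'   rate of 1 ha/LSU (the expected count scales with 1/effectiveSr).
#' @param ldSeed seed-bank input deposited by one long-distance event.
#' @param seedSurvival fraction of the annual-grass seed bank surviving
#'   the dry season.
#' @param extinctCover local extinction floor: per-cell cover below this
#'   is cleared at the end of the season.
#' @param pEstAnnual establishment probability for annual grasses, whose
#'   entire cover regrows from seed each season.
#' @param pEstShrub establishment probability for shrub seedlings.
#' @param shrubSeedFactor viable-seedling fraction of the local shrub
#'   kernel input (shrub recruitment is mainly herbivore-mediated).
#' @param annualSeedYield seed-bank production of annual grasses per unit
#'   dispersed cover.
#' @return named list of constants.
#' @export
vegConstants <- function(wue = 0.025, b0 = 0.25, pEst = 0.02,
                         estMargin = 0.01, quantum = 0.002,
                         kernelMean = 1, ldRate = 6, ldSeed = 5,
                         seedSurvival = 1.0, extinctCover = 1e-4,
                         pEstAnnual = 0.05, pEstShrub = 0.02,
                         shrubSeedFactor = 0.1, annualSeedYield = 3) {
  list(wue = wue, b0 = b0, pEst = pEst, estMargin = estMargin,
       quantum = quantum, kernelMean = kernelMean, ldRate = ldRate,
       ldSeed = ldSeed, seedSurvival = seedSurvival,
       extinctCover = extinctCover, pEstAnnual = pEstAnnual,
       pEstShrub = pEstShrub, shrubSeedFactor = shrubSeedFactor,
       annualSeedYield = annualSeedYield)
}

#' Biweekly cover growth from transpiration
#'
#' `Delta cover = tVeg * wue * transpiration * freeSpace`, capped at the
#' meta-PFT biweekly growth maximum and at the available free space. No
#' water, no growth; no space, no growth.
#'
#' @param cover current cover fraction (unused by the increment rule but
#'   kept for signature clarity; growth is transpiration-driven and
#'   transpiration already scales with cover).
#' @param transpBiweek transpiration of the type over the biweek, mm.
#' @param strategy one-row strategy data.frame (columns `tVeg`, `maxGrow`).
#' @param freeSpace free cover fraction in \[0, 1\].
#' @param wue water-use efficiency, cover per mm.
#' @return cover increment (vectorized over cells).
#' @export
grow <- function(cover, transpBiweek, strategy, freeSpace, wue = 0.025) {
  inc <- strategy$tVeg * wue * transpBiweek * freeSpace
  pmin(pmin(inc, strategy$maxGrow), freeSpace)
}

#' End-of-season mortality
#'
#' Cover is reduced once per growing season by a background senescence share
#' plus a water-stress share:
#' `cover' = cover * (1 - mrd*b0 - mrd*(1-b0)*stressFrac)`, clipped at 0.
#' Annual grasses die back completely and regrow from seed.
#'
#' @param cover cover fraction(s).
#' @param stressFrac fraction of growing-season days with root-weighted soil
#'   moisture below the type's wilting point, in \[0, 1\].
#' @param strategy one-row strategy data.frame (columns `mrd`, `meta`).
#' @param b0 background-senescence share of `mrd`.
#' @return surviving cover.
#' @export
endSeasonMortality <- function(cover, stressFrac, strategy, b0 = 0.25) {
  if (any(stressFrac < 0 | stressFrac > 1)) stop("stressFrac must lie in [0,1]")
  if (strategy$meta == "annual") return(cover * 0)
  rate <- strategy$mrd * b0 + strategy$mrd * (1 - b0) * stressFrac
  pmax(cover * (1 - rate), 0)
}

# Weighted neighbourhood mean with closed boundaries; weights renormalized
# per cell so a uniform field is a fixed point. Thin wrapper over the
# compiled kernel.
.neighbourhoodMean <- function(mat, offsets, weights) {
  out <- .kernelMeanCpp(matrix(as.numeric(mat), ncol = 1L), nrow(mat),
                        ncol(mat), offsets, weights)
  matrix(out, nrow(mat), ncol(mat))
}

# Grass dispersal neighbourhood: the focal cell plus its nearest neighbours,
# weighted so the effective source area is 150 m2 (6 cells of 25 m2): focal
# and the 4 orthogonal neighbours with weight 1, the 4 diagonals with 1/4.
.grassOffsets <- function() {
  off <- rbind(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
               c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  storage.mode(off) <- "integer"
  list(offsets = off, weights = c(rep(1, 5), rep(0.25, 4)))
}

# Local shrub kernel: exponential decay with distance, e-folding
# `kernelMean` cells, truncated at radius 2.
.shrubOffsets <- function(kernelMean = 1) {
  g <- expand.grid(di = -2:2, dj = -2:2)
  d <- sqrt(g$di^2 + g$dj^2)
  off <- as.matrix(g)
  storage.mode(off) <- "integer"
  list(offsets = off, weights = exp(-d / kernelMean))
}

#' Seed dispersal
#'
#' Grass types (perennial and annual) disperse uniformly within a 150 m2
#' neighbourhood of the focal cell. Shrubs disperse through a local
#' exponential kernel plus herbivore-mediated long-distance events whose
#' expected number scales with animal density (1 / effective stocking
#' rate). Uses the current RNG stream; deterministic under a fixed seed.
#'
#' @param cover matrix (cells x types) of cover fractions, cells in
#'   column-major order of an `nr x nc` grid.
#' @param strategies strategy table matching the columns of `cover`.
#' @param effectiveSr effective stocking rate (ha/LSU); `Inf` disables
#'   herbivore-mediated events.
#' @param nr,nc grid shape.
#' @param constants list from [vegConstants()].
#' @return seed-bank matrix (cells x types), dimensionless.
#' @export
disperse <- function(cover, strategies, effectiveSr, nr, nc,
                     constants = vegConstants()) {
  if (!is.infinite(effectiveSr) && effectiveSr <= 0)
    stop("effectiveSr must be positive")
  ncell <- nr * nc
  seed <- matrix(0, ncell, ncol(cover), dimnames = dimnames(cover))
  go <- .grassOffsets()
  so <- .shrubOffsets(constants$kernelMean)
  isShrub <- strategies$meta == "shrub"
  grass <- which(!isShrub & colSums(cover) > 0)
  shrub <- which(isShrub & colSums(cover) > 0)
  if (length(grass))
    seed[, grass] <- .kernelMeanCpp(cover[, grass, drop = FALSE], nr, nc,
                                    go$offsets, go$weights)
  if (length(shrub)) {
    seed[, shrub] <- constants$shrubSeedFactor *
      .kernelMeanCpp(cover[, shrub, drop = FALSE], nr, nc,
                     so$offsets, so$weights)
    if (is.finite(effectiveSr)) {
      # herbivore-mediated long-distance events (per biweek), expected
      # count proportional to animal density 1/effectiveSr
      for (t in shrub) {
        meanCov <- mean(cover[, t])
        nEvents <- rpois(1L, ncell * constants$ldRate * meanCov /
                           effectiveSr)
        if (nEvents > 0L) {
          targets <- sample.int(ncell, nEvents, replace = TRUE)
          for (tc in targets)
            seed[tc, t] <- seed[tc, t] + constants$ldSeed
        }
      }
    }
  }
  seed
}

#' Establishment of dispersed seeds
#'
#' Seeds translate into new cover only where the biweekly mean upper-layer
#' moisture exceeds the type's wilting point by an establishment margin.
#' The expected increment is `pEst * seedBank * freeSpace`; stochastic
#' rounding to a small cover quantum avoids systematic extinction bias at
#' low densities. Uses the current RNG stream.
#'
#' @param seedBank matrix (cells x types).
#' @param thetaUpperMean biweekly mean upper-layer moisture per cell.
#' @param freeSpace free cover fraction per cell.
#' @param strategies strategy table matching the columns of `seedBank`.
#' @param constants list from [vegConstants()].
#' @return matrix of cover increments (cells x types).
#' @export
establish <- function(seedBank, thetaUpperMean, freeSpace, strategies,
                      constants = vegConstants()) {
  ncell <- nrow(seedBank)
  q <- constants$quantum
  inc <- matrix(0, ncell, ncol(seedBank), dimnames = dimnames(seedBank))
  active <- which(colSums(seedBank) > 0)
  if (length(active) == 0L) return(inc)
  pEst <- c(annual = constants$pEstAnnual, shrub = constants$pEstShrub,
            perennial = constants$pEst)[strategies$meta[active]]
  wet <- outer(thetaUpperMean,
               strategies$wiltingPoint[active] + constants$estMargin, ">")
  mu <- rep(pEst, each = ncell) * seedBank[, active, drop = FALSE] *
    freeSpace * wet
  n <- mu / q
  fl <- floor(n)
  inc[, active] <- q * (fl + (runif(length(n)) < n - fl))
  inc
}

# Scale competing per-type increments so a cell's total cover stays <= 1.
.scaleToFreeSpace <- function(inc, freeSpace) {
  tot <- rowSums(inc)
  over <- tot > freeSpace & tot > 0
  if (any(over)) inc[over, ] <- inc[over, , drop = FALSE] *
      (freeSpace[over] / tot[over])
  inc
}

#' One biweekly vegetation step
#'
#' Applies growth, dispersal and establishment for every cell and type
#' within the wet season. Per-cell total cover never exceeds 1; increments
#' competing for the same free space are scaled proportionally. Strategy
#' types listed in `staticTypes` keep their cover frozen (they still
#' transpire and occupy space).
#'
#' @param veg list with matrices `cover` and `seedBank` (cells x types).
#' @param transpBiweek matrix (cells x types) of biweekly transpiration, mm.
#' @param thetaUpperMean biweekly mean upper-layer moisture per cell.
#' @param strategies strategy table matching the columns of `veg$cover`.
#' @param effectiveSr effective stocking rate for shrub dispersal (ha/LSU).
#' @param nr,nc grid shape.
#' @param constants list from [vegConstants()].
#' @param staticTypes character ids of types with frozen cover.
#' @return updated `veg` list.
#' @export
stepBiweek <- function(veg, transpBiweek, thetaUpperMean, strategies,
                       effectiveSr, nr, nc, constants = vegConstants(),
                       staticTypes = character()) {
  cover <- veg$cover
  if (any(cover < 0) || any(rowSums(cover) > 1 + 1e-9))
    stop("invalid cover state")
  dynamic <- !(strategies$id %in% staticTypes)

  # compiled fast path for growth (shared per-meta cap, free-space budget)
  metaIdx <- match(strategies$meta, unique(strategies$meta)) - 1L
  cover <- .growStepCpp(cover, transpBiweek, metaIdx, strategies$tVeg,
                        strategies$maxGrow, dynamic, constants$wue)

  seedBank <- disperse(cover, strategies, effectiveSr, nr, nc, constants)
  # annual grasses die back completely each season and regrow from seed:
  # their bank reflects this season's seed production (yield x dispersed
  # cover) once it exceeds the carried-over bank, which itself decays at
  # the end of each season
  ann <- strategies$meta == "annual"
  if (any(ann))
    seedBank[, ann] <- pmax(
      constants$annualSeedYield * seedBank[, ann, drop = FALSE],
      veg$seedBank[, ann, drop = FALSE])

  pEstVec <- c(annual = constants$pEstAnnual, shrub = constants$pEstShrub,
               perennial = constants$pEst)[strategies$meta]
  cover <- .establishCpp(cover, seedBank, thetaUpperMean,
                         strategies$wiltingPoint, unname(pEstVec), dynamic,
                         constants$estMargin, constants$quantum)

  list(cover = cover, seedBank = seedBank)
}
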