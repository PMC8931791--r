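# Daily surface-water and two-layer soil-moisture dynamics per grid cell.
# The exported functions below are the reference (pure R) implementation of
# the process chain; the compiled core (.hydroPeriodCpp) reproduces them
# bit-for-bit over multi-day periods and is used by the scenario runner.

#' Hydrology process constants
#'
#' Landscape process constants: the bare-soil fraction of saturated
#' conductivity (infiltration-cover feedback), runoff roughness damping per
#' unit cover, and evaporation shading per unit cover. Overridable via
#' `scenarioConfig(hydroConstants = ...)`.
#'
#' @param infiltrationBare bare-soil fraction `c0` of conductivity.
#' @param roughness runoff damping `r` per unit cover, in (0, 1\].
#' @param shading evaporation shading `s` per unit cover, in \[0, 1\].
#' @param stressThreshold a growing-season day counts as a water-stress
#'   day for a type when its root-weighted uptake ability
#'   `sum_l rootFrac_l * g(theta_l)` falls below this value.
#' @return named numeric vector.
#' @export
hydroConstants <- function(infiltrationBare = 0.4, roughness = 0.8,
                           shading = 0.85, stressThreshold = 0.25) {
  c(infiltrationBare = infiltrationBare, roughness = roughness,
    shading = shading, stressThreshold = stressThreshold)
}

.hydroConstants <- hydroConstants

# Uptake groups: types sharing a wilting point and root profile see the
# same water-limitation and rationing terms, so the compiled core tracks
# per-group sums and per-type transpiration is reconstructed exactly for
# any period of constant cover.
.typeGroups <- function(strategies) {
  key <- paste(strategies$wiltingPoint, strategies$rootUpper,
               strategies$rootLower)
  grp <- match(key, unique(key))
  first <- !duplicated(key)
  list(groupOf = as.integer(grp - 1L),
       wp = strategies$wiltingPoint[first],
       rfU = strategies$rootUpper[first],
       rfL = strategies$rootLower[first])
}

# Run the compiled core for a span of days with fixed cover; optionally
# reconstruct the per-type transpiration sums.
.hydroPeriod <- function(thetaU, thetaL, surface, cover, strategies, groups,
                         precip, temp, doy, inSeason, receiver, soilVec,
                         constants, perType = FALSE, coverUptake = NULL,
                         totCover = NULL) {
  ncell <- nrow(cover)
  if (is.null(coverUptake))
    coverUptake <- cover * rep(strategies$uptakeRate, each = ncell)
  if (is.null(totCover)) totCover <- rowSums(cover)
  h <- .hydroPeriodCpp(thetaU, thetaL, surface, coverUptake,
                       groups$groupOf, groups$wp, groups$rfU, groups$rfL,
                       precip, temp, as.integer(doy), inSeason,
                       receiver, soilVec, constants, totCover)
  if (perType) {
    G <- length(groups$wp)
    gi <- groups$groupOf + 1L   # group index per type
    h$transpType <- coverUptake *
      (rep(strategies$rootUpper, each = ncell) *
         h$groupS[, gi, drop = FALSE] +
       rep(strategies$rootLower, each = ncell) *
         h$groupS[, G + gi, drop = FALSE])
  }
  h
}

#' Potential evapotranspiration (Hargreaves-type)
#'
#' `PET = max(0, 0.0023 * Ra(doy) * (temp + 17.8))` with a fixed seasonal
#' radiation proxy for a southern-hemisphere site (maximum at the December
#' solstice) that folds in a constant diurnal temperature-range term.
#'
#' @param temp daily mean temperature (degC).
#' @param doy calendar day-of-year (1 = 1 January).
#' @return potential evapotranspiration, mm/day.
#' @export
petDaily <- function(temp, doy) {
  ra <- (14 + 3.5 * cos(2 * pi * (doy - 355) / 365)) * sqrt(8)
  pmax(0, 0.0023 * ra * (temp + 17.8))
}

#' Infiltration of surface water into the upper soil layer
#'
#' Infiltration is the minimum of available surface water, remaining storage
#' capacity of the upper layer, and an effective conductivity that increases
#' with vegetation cover (plant roots increase soil porosity):
#' `Ksat_eff = Ksat * (c0 + (1 - c0) * cover)`.
#'
#' @param surfaceWater ponded water, mm.
#' @param totalCover total vegetation cover fraction in \[0, 1\].
#' @param soil a [SoilParams-class].
#' @param thetaUpper upper-layer volumetric moisture.
#' @param infiltrationBare bare-soil fraction `c0` of conductivity.
#' @return infiltrated depth, mm (vectorized over cells).
#' @export
infiltrate <- function(surfaceWater, totalCover, soil, thetaUpper,
                       infiltrationBare = 0.4) {
  if (any(totalCover < 0 | totalCover > 1)) stop("cover must lie in [0, 1]")
  ksatEff <- soil@satConductivity *
    (infiltrationBare + (1 - infiltrationBare) * totalCover)
  cap <- pmax(0, (soil@porosity - thetaUpper) * soil@depthUpper)
  pmax(0, pmin(surfaceWater, pmin(cap, ksatEff)))
}

# Steepest-descent receiver (0-based linear index, -1 = pit/flat) for every
# cell of a DEM, 8-neighbourhood, closed lateral boundaries.
.receiverIndex <- function(dem) {
  z <- dem@elevation
  nr <- nrow(z); nc <- ncol(z)
  recv <- matrix(-1L, nr, nc)
  if (max(z) - min(z) == 0) return(as.integer(recv))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- 0; bi <- -1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      drop <- (z[i, j] - z[ii, jj]) / sqrt(di^2 + dj^2)
      if (drop > best) { best <- drop; bi <- (jj - 1L) * nr + (ii - 1L) }
    }
    recv[i, j] <- bi
  }
  as.integer(recv)
}

#' Lateral routing of surface runoff
#'
#' Each cell's surface water moves to its steepest-descent neighbour
#' (8-neighbourhood), damped by a vegetation roughness factor
#' `(1 - r * cover)`. Flat or pit cells retain their water and boundaries
#' are closed, so total surface water is conserved across the grid.
#'
#' @param surfaceGrid matrix of surface water, mm.
#' @param dem a [TerrainGrid-class] congruent with `surfaceGrid`.
#' @param coverGrid matrix of total vegetation cover.
#' @param roughness damping coefficient `r` in (0, 1\].
#' @return list with matrices `surface` (after routing), `runoffOut` and
#'   `runonIn` (mm moved out of / into each cell).
#' @export
routeRunoff <- function(surfaceGrid, dem, coverGrid, roughness = 0.8) {
  stopifnot(is(dem, "TerrainGrid"))
  if (!all(dim(surfaceGrid) == dim(dem@elevation)) ||
      !all(dim(coverGrid) == dim(dem@elevation)))
    stop("grid shapes do not match")
  recv <- .receiverIndex(dem)
  out <- numeric(length(surfaceGrid))
  s <- as.numeric(surfaceGrid)
  cv <- pmin(as.numeric(coverGrid), 1)
  movable <- recv >= 0L & s > 0
  out[movable] <- s[movable] * (1 - roughness * cv[movable])
  runon <- numeric(length(s))
  if (any(movable)) {
    tgt <- recv[movable] + 1L
    runon <- runon + as.numeric(
      tapply(out[movable], factor(tgt, levels = seq_along(s)), sum,
             default = 0))
    runon[is.na(runon)] <- 0
  }
  newS <- s - out + runon
  list(surface = matrix(newS, nrow(surfaceGrid)),
       runoffOut = matrix(out, nrow(surfaceGrid)),
       runonIn = matrix(runon, nrow(surfaceGrid)))
}

#' Bare-soil evaporation from the upper layer
#'
#' `E = PET * evaporationConstant * relative wetness * (1 - s * cover)`,
#' where relative wetness is `(theta - residual) / (fc - residual)` clipped
#' to \[0, 1\]; evaporation never draws the layer below residual moisture.
#'
#' @param thetaUpper upper-layer volumetric moisture.
#' @param totalCover total vegetation cover fraction.
#' @param temp daily mean temperature (degC).
#' @param soil a [SoilParams-class].
#' @param doy calendar day-of-year for the radiation proxy.
#' @param shading shading coefficient `s` per unit cover.
#' @return evaporation, mm/day (vectorized).
#' @export
evaporate <- function(thetaUpper, totalCover, temp, soil, doy = 15L,
                      shading = 0.85) {
  wet <- .clip((thetaUpper - soil@residualWater) /
                 (soil@fcUpper - soil@residualWater), 0, 1)
  e <- petDaily(temp, doy) * soil@evaporationConstant * wet *
    (1 - shading * pmin(totalCover, 1))
  pmin(pmax(e, 0), pmax(0, (thetaUpper - soil@residualWater) * soil@depthUpper))
}

#' Transpiration per strategy type and soil layer
#'
#' Demand of type t in layer l is
#' `PET * cover_t * uptakeRate_t * rootFrac_{t,l} * g(theta_l)`, with `g`
#' rising linearly from 0 at the type's wilting point to 1 at field
#' capacity. Annual grasses have no roots in the lower layer. When total
#' demand in a layer exceeds the water extractable above the wilting point,
#' all uptake is rationed proportionally.
#'
#' @param thetaUpper,thetaLower volumetric moisture of the two layers
#'   (single cell).
#' @param coverByType named numeric vector of cover per strategy type.
#' @param strategies strategy table from [assembleStrategyTypes()] (rows
#'   matching `names(coverByType)`).
#' @param temp daily mean temperature (degC).
#' @param soil a [SoilParams-class].
#' @param doy calendar day-of-year.
#' @return matrix (types x 2) of transpiration per layer, mm/day.
#' @export
transpire <- function(thetaUpper, thetaLower, coverByType, strategies, temp,
                      soil, doy = 15L) {
  if (!all(names(coverByType) %in% strategies$id))
    stop("unknown strategy type in coverByType")
  st <- strategies[names(coverByType), ]
  pet <- petDaily(temp, doy)
  out <- matrix(0, length(coverByType), 2L,
                dimnames = list(names(coverByType), c("upper", "lower")))
  for (layer in 1:2) {
    th <- if (layer == 1L) thetaUpper else thetaLower
    dd <- if (layer == 1L) soil@depthUpper else soil@depthLower
    fc <- if (layer == 1L) soil@fcUpper else soil@fcLower
    rf <- if (layer == 1L) st$rootUpper else st$rootLower
    g <- ifelse(fc > st$wiltingPoint,
                .clip((th - st$wiltingPoint) / (fc - st$wiltingPoint), 0, 1),
                0)
    dem <- pet * coverByType * st$uptakeRate * rf * g
    demand <- sum(dem)
    if (demand > 0) {
      minwp <- min(st$wiltingPoint[dem > 0])
      avail <- max(0, (th - minwp) * dd)
      f <- if (demand > avail) avail / demand else 1
      out[, layer] <- dem * f
    }
  }
  out
}

#' One day of coupled surface/soil water dynamics on the grid
#'
#' Applies, in order: precipitation, infiltration, runoff routing,
#' percolation of upper-layer excess over field capacity, slow downward
#' diffusion, evaporation (upper layer), and transpiration (both layers).
#' The per-cell water balance closes to numerical precision:
#' `Delta storage = precip + runon - runoff - deep drainage - E - T`.
#'
#' @param state list with matrices `surface` (mm), `thetaUpper`,
#'   `thetaLower` (vol fraction).
#' @param precip daily precipitation, mm.
#' @param temp daily mean temperature, degC.
#' @param doy calendar day-of-year.
#' @param cover matrix (cells x types) of cover fractions; cells in
#'   column-major grid order.
#' @param strategies strategy table matching the columns of `cover`.
#' @param soil a [SoilParams-class].
#' @param dem a [TerrainGrid-class].
#' @param constants named vector from the internal hydrology constants
#'   (infiltrationBare, roughness, shading).
#' @return list with `state` (updated) and `fluxes` (per-cell vectors:
#'   infiltration, runoffOut, runonIn, percolation, deepDrainage, diffusion,
#'   evaporation, transpiration; plus matrix `transpByType`).
#' @export
stepDay <- function(state, precip, temp, doy, cover, strategies, soil, dem,
                    constants = .hydroConstants()) {
  if (any(!is.finite(state$thetaUpper)) || any(!is.finite(state$thetaLower)) ||
      any(!is.finite(state$surface)))
    stop("non-finite values in hydrological state")
  nr <- nrow(state$surface); ncell <- length(state$surface)
  totcov <- matrix(rowSums(cover), nr)

  surface <- state$surface + precip
  infil <- matrix(
    infiltrate(as.numeric(surface), pmin(as.numeric(totcov), 1), soil,
               as.numeric(state$thetaUpper),
               constants[["infiltrationBare"]]), nr)
  surface <- surface - infil
  thetaU <- state$thetaUpper + infil / soil@depthUpper

  routed <- routeRunoff(surface, dem, totcov, constants[["roughness"]])
  surface <- routed$surface

  perc <- pmin(pmax((thetaU - soil@fcUpper) * soil@depthUpper, 0),
               soil@satConductivity)
  perc <- pmin(perc, (soil@porosity - state$thetaLower) * soil@depthLower)
  thetaU <- thetaU - perc / soil@depthUpper
  thetaL <- state$thetaLower + perc / soil@depthLower

  deep <- pmin(pmax((thetaL - soil@fcLower) * soil@depthLower, 0),
               soil@satConductivity)
  thetaL <- thetaL - deep / soil@depthLower

  dif <- matrix(0, nr, ncol(state$surface))
  if (soil@diffusionCoeff > 0) {
    can <- thetaU > thetaL
    dif[can] <- pmin(soil@diffusionCoeff,
                     (thetaU[can] - soil@residualWater) * soil@depthUpper)
    dif[can] <- pmin(dif[can],
                     (soil@porosity - thetaL[can]) * soil@depthLower)
    dif <- pmax(dif, 0)
    thetaU <- thetaU - dif / soil@depthUpper
    thetaL <- thetaL + dif / soil@depthLower
  }

  ev <- matrix(
    evaporate(as.numeric(thetaU), as.numeric(totcov), temp, soil, doy,
              constants[["shading"]]), nr)
  thetaU <- thetaU - ev / soil@depthUpper

  transpByType <- matrix(0, ncell, nrow(strategies),
                         dimnames = list(NULL, strategies$id))
  transp <- numeric(ncell)
  thU <- as.numeric(thetaU); thL <- as.numeric(thetaL)
  pet <- petDaily(temp, doy)
  for (layer in 1:2) {
    th <- if (layer == 1L) thU else thL
    dd <- if (layer == 1L) soil@depthUpper else soil@depthLower
    fc <- if (layer == 1L) soil@fcUpper else soil@fcLower
    rf <- if (layer == 1L) strategies$rootUpper else strategies$rootLower
    wp <- strategies$wiltingPoint
    gT <- outer(wp, th, function(w, x) x - w) / pmax(fc - wp, 1e-12)
    g <- t(.clip(gT, 0, 1))                   # ncell x ntype
    dem <- g * cover *
      rep(pet * strategies$uptakeRate * rf, each = ncell)
    demand <- rowSums(dem)
    pos <- demand > 0
    if (any(pos)) {
      minwp <- apply(dem[pos, , drop = FALSE], 1L,
                     function(d) min(wp[d > 0]))
      avail <- pmax(0, (th[pos] - minwp) * dd)
      f <- ifelse(demand[pos] > avail, avail / demand[pos], 1)
      take <- dem[pos, , drop = FALSE] * f
      transpByType[pos, ] <- transpByType[pos, , drop = FALSE] + take
      taken <- rowSums(take)
      th[pos] <- th[pos] - taken / dd
      transp[pos] <- transp[pos] + taken
    }
    if (layer == 1L) thU <- th else thL <- th
  }

  list(
    state = list(surface = surface, thetaUpper = matrix(thU, nr),
                 thetaLower = matrix(thL, nr)),
    fluxes = list(
      infiltration = as.numeric(infil),
      runoffOut = as.numeric(routed$runoffOut),
      runonIn = as.numeric(routed$runonIn),
      percolation = as.numeric(perc), deepDrainage = as.numeric(deep),
      diffusion = as.numeric(dif), evaporation = as.numeric(ev),
      transpiration = transp, transpByType = transpByType)
  )
}
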