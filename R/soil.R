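# Soil parameterization: a two-layer bucket profile (upper 0-200 mm, lower
# 200-1000 mm by default) with texture-class presets and an RMSE-based
# calibration harness against observed soil-moisture series.

#' Soil parameters of the two-layer profile
#'
#' @slot depthUpper,depthLower layer thicknesses (mm).
#' @slot porosity saturated volumetric water content (vol fraction).
#' @slot fcUpper,fcLower field capacity per layer (vol fraction).
#' @slot residualWater residual water content (vol fraction).
#' @slot soilWiltingPoint soil wilting point (vol fraction); distinct from
#'   the per-strategy plant wilting points.
#' @slot satConductivity saturated hydraulic conductivity (mm/day).
#' @slot evaporationConstant dimensionless scaling of bare-soil evaporation
#'   in \[0, 1\] (accounts for e.g. soil crusts).
#' @slot diffusionCoeff slow upper-to-lower diffusion flux (mm/day).
#' @slot textureLabel free-text texture class.
#' @export
setClass("SoilParams",
  representation(
    depthUpper = "numeric", depthLower = "numeric", porosity = "numeric",
    fcUpper = "numeric", fcLower = "numeric", residualWater = "numeric",
    soilWiltingPoint = "numeric", satConductivity = "numeric",
    evaporationConstant = "numeric", diffusionCoeff = "numeric",
    textureLabel = "character"
  )
)

setValidity("SoilParams", function(object) {
  msg <- character()
  if (object@depthUpper <= 0 || object@depthLower <= 0)
    msg <- c(msg, "layer depths must be positive")
  ordered <- object@residualWater < object@soilWiltingPoint &&
    object@soilWiltingPoint < min(object@fcUpper, object@fcLower) &&
    max(object@fcUpper, object@fcLower) < object@porosity
  if (!ordered)
    msg <- c(msg, "need residualWater < soilWiltingPoint < fieldCapacity < porosity")
  if (object@diffusionCoeff < 0) msg <- c(msg, "diffusionCoeff must be >= 0")
  if (object@evaporationConstant < 0 || object@evaporationConstant > 1)
    msg <- c(msg, "evaporationConstant must lie in [0, 1]")
  if (object@satConductivity <= 0) msg <- c(msg, "satConductivity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create soil parameters (loamy-sand preset)
#'
#' Defaults follow published pedotransfer values for the loamy-sand texture
#' class; every value can be overridden.
#'
#' @param depthUpper,depthLower layer thicknesses in mm.
#' @param porosity,fcUpper,fcLower,residualWater,soilWiltingPoint volumetric
#'   fractions.
#' @param satConductivity saturated conductivity, mm/day.
#' @param evaporationConstant evaporation scaling in \[0,1\].
#' @param diffusionCoeff upper-to-lower diffusion, mm/day.
#' @param textureLabel texture class label.
#' @return a validated [SoilParams-class].
#' @export
soilParams <- function(depthUpper = 200, depthLower = 800,
                       porosity = 0.437, fcUpper = 0.125, fcLower = 0.125,
                       residualWater = 0.035, soilWiltingPoint = 0.055,
                       satConductivity = 1500, evaporationConstant = 0.16,
                       diffusionCoeff = 0.05,
                       textureLabel = "loamy sand") {
  new("SoilParams", depthUpper = depthUpper, depthLower = depthLower,
      porosity = porosity, fcUpper = fcUpper, fcLower = fcLower,
      residualWater = residualWater, soilWiltingPoint = soilWiltingPoint,
      satConductivity = satConductivity,
      evaporationConstant = evaporationConstant,
      diffusionCoeff = diffusionCoeff, textureLabel = textureLabel)
}

setMethod("show", "SoilParams", function(object) {
  cat(sprintf(
    "SoilParams (%s): layers %g/%g mm; porosity %.3f; fc %.3f/%.3f; Ksat %g mm/d\n",
    object@textureLabel, object@depthUpper, object@depthLower,
    object@porosity, object@fcUpper, object@fcLower, object@satConductivity))
})

# Named vector form consumed by the C++ core and the R reference step.
.soilVector <- function(soil) {
  c(depthUpper = soil@depthUpper, depthLower = soil@depthLower,
    porosity = soil@porosity, fcUpper = soil@fcUpper, fcLower = soil@fcLower,
    residualWater = soil@residualWater,
    satConductivity = soil@satConductivity,
    evaporationConstant = soil@evaporationConstant,
    diffusionCoeff = soil@diffusionCoeff)
}

#' Simulate soil moisture for a single uniform cell
#'
#' Runs the daily hydrology for one cell with a fixed generic vegetation
#' cover; used by the soil calibration harness.
#'
#' @param soil a [SoilParams-class].
#' @param climate a [ClimateSeries-class].
#' @param cover fixed total vegetation cover fraction.
#' @return data.frame with daily `thetaUpper` and `thetaLower` (vol
#'   fraction).
#' @export
simulateSoilMoisture <- function(soil, climate, cover = 0.3) {
  stopifnot(is(soil, "SoilParams"), is(climate, "ClimateSeries"))
  n <- length(climate@precip)
  doy <- .calendarDoy(((seq_len(n) - 1L) %% 365L) + 1L)
  # generic vegetation: one type with perennial-like uptake traits
  gen <- data.frame(uptakeRate = 0.9, wiltingPoint = 0.077,
                    rootUpper = 0.7, rootLower = 0.3)
  out <- .hydroPeriod(
    soil@fcUpper, soil@fcLower, 0, matrix(cover, 1L, 1L), gen,
    .typeGroups(gen), climate@precip, climate@temp, doy,
    rep(FALSE, n), -1L, .soilVector(soil), .hydroConstants())
  data.frame(thetaUpper = out$thetaUDaily, thetaLower = out$thetaLDaily)
}

#' Calibrate soil parameters against observed soil moisture
#'
#' Runs the hydrology model for every candidate parameter set and returns
#' the set minimizing the root mean square error between simulated and
#' observed volumetric soil moisture (both layers pooled). Ties are broken
#' by the first-encountered candidate in the deterministic scan order.
#'
#' @param observed data.frame with columns `thetaUpper` and `thetaLower`
#'   (vol fraction), one row per day of `climate`.
#' @param candidates data.frame of candidate parameter values; column names
#'   must match [soilParams()] argument names.
#' @param climate a [ClimateSeries-class] covering the observation period.
#' @param cover fixed vegetation cover used in the simulation.
#' @param base a [SoilParams-class] supplying values not in `candidates`.
#' @return list with elements `soil` (the winning [SoilParams-class]),
#'   `rmse`, and `rmseAll` (per-candidate RMSE in scan order).
#' @export
calibrateSoil <- function(observed, candidates, climate, cover = 0.3,
                          base = soilParams()) {
  if (NROW(observed) == 0L) stop("empty observed series")
  if (NROW(candidates) == 0L) stop("empty candidate set")
  if (NROW(observed) != length(climate@precip))
    stop("observed series and climate must cover the same days")
  rmseAll <- numeric(nrow(candidates))
  soils <- vector("list", nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    args <- as.list(candidates[k, , drop = FALSE])
    soilK <- do.call(soilParams, utils::modifyList(
      .soilParamsArgs(base), args))
    sim <- simulateSoilMoisture(soilK, climate, cover)
    dev <- c(sim$thetaUpper - observed$thetaUpper,
             sim$thetaLower - observed$thetaLower)
    rmseAll[k] <- sqrt(mean(dev^2))
    soils[[k]] <- soilK
  }
  best <- which.min(rmseAll)  # which.min takes the first minimum: tie-break
  list(soil = soils[[best]], rmse = rmseAll[best], rmseAll = rmseAll)
}

.soilParamsArgs <- function(soil) {
  list(depthUpper = soil@depthUpper, depthLower = soil@depthLower,
       porosity = soil@porosity, fcUpper = soil@fcUpper,
       fcLower = soil@fcLower, residualWater = soil@residualWater,
       soilWiltingPoint = soil@soilWiltingPoint,
       satConductivity = soil@satConductivity,
       evaporationConstant = soil@evaporationConstant,
       diffusionCoeff = soil@diffusionCoeff,
       textureLabel = soil@textureLabel)
}
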