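# Land-use scenario experiment: 100-year runs of the coupled
# hydrology-vegetation-herbivory model on a 30 x 30 grid of 5 x 5 m cells,
# replicated over stochastic climate series.

#' Land-use scenario configuration
#'
#' @slot landUse `"grazing"` or `"browsing"`.
#' @slot stockingRate stocking rate, ha/LSU (50/40/30/20/10 = very low to
#'   very high herbivore density).
#' @slot years simulation duration (yr).
#' @slot replicates number of climate replicates.
#' @slot gridRows,gridCols,cellSize grid shape; cell edge in m.
#' @slot initCover named initial cover per meta-PFT (fractions).
#' @slot masterSeed integer master seed; replicate substreams derive from it.
#' @slot mapRef reference mean annual precipitation for the rainfall
#'   correction factor (mm).
#' @slot soil a [SoilParams-class].
#' @slot options list of overrides: `strategies` (custom community table),
#'   `staticTypes` (frozen-cover ids), `vegConstants`, `hydroConstants`,
#'   `dem` (a [TerrainGrid-class]), `bodyWeight`, `intakeFrac`.
#' @export
setClass("ScenarioConfig",
  representation(
    landUse = "character", stockingRate = "numeric", years = "integer",
    replicates = "integer", gridRows = "integer", gridCols = "integer",
    cellSize = "numeric", initCover = "numeric", masterSeed = "integer",
    mapRef = "numeric", soil = "SoilParams", options = "list"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (!object@landUse %in% c("grazing", "browsing"))
    msg <- c(msg, "landUse must be 'grazing' or 'browsing'")
  if (object@stockingRate <= 0) msg <- c(msg, "stockingRate must be positive")
  if (object@years < 1L) msg <- c(msg, "years must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (any(object@initCover < 0) || sum(object@initCover) > 1)
    msg <- c(msg, "initial covers must be non-negative and sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' Create a scenario configuration
#'
#' Defaults describe the study design: a 2.25 ha landscape of 30 x 30 cells
#' (5 x 5 m), 100 years, 30 climate replicates, shrubs and perennials
#' initialized at 20% meta-PFT cover (split equally among their strategy
#' types) and annuals at 5%.
#'
#' @param landUse `"grazing"` or `"browsing"`.
#' @param stockingRate ha/LSU.
#' @param years,replicates run length and number of climate replicates.
#' @param gridRows,gridCols,cellSize grid geometry.
#' @param initCover named vector with elements `shrub`, `perennial`,
#'   `annual`.
#' @param masterSeed integer master seed.
#' @param mapRef reference MAP (mm) for the rainfall correction.
#' @param soil a [SoilParams-class].
#' @param ... entries for the `options` slot (see
#'   [ScenarioConfig-class]).
#' @return a validated [ScenarioConfig-class].
#' @export
scenarioConfig <- function(landUse = c("grazing", "browsing"),
                           stockingRate = 40,
                           years = 100L, replicates = 30L,
                           gridRows = 30L, gridCols = 30L, cellSize = 5,
                           initCover = c(shrub = 0.20, perennial = 0.20,
                                         annual = 0.05),
                           masterSeed = 1L, mapRef = 291.3,
                           soil = soilParams(), ...) {
  landUse <- match.arg(landUse)
  new("ScenarioConfig", landUse = landUse, stockingRate = stockingRate,
      years = as.integer(years), replicates = as.integer(replicates),
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      cellSize = cellSize, initCover = initCover,
      masterSeed = as.integer(masterSeed), mapRef = mapRef, soil = soil,
      options = list(...))
}

#' Landscape area of a scenario (ha)
#' @param config a [ScenarioConfig-class].
#' @export
scenarioArea <- function(config) {
  config@gridRows * config@gridCols * config@cellSize^2 / 1e4
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %s at %g ha/LSU; %d x %d cells (%.2f ha); %d yr x %d reps\n",
    object@landUse, object@stockingRate, object@gridRows, object@gridCols,
    scenarioArea(object), object@years, object@replicates))
})

#' Per-year, per-replicate simulation output
#'
#' @slot annual data.frame with one row per replicate x year: per-type
#'   grid-mean cover (%, columns `cover.<id>`), `total_cover`,
#'   transpiration and evaporation sums (mm), `tet` (upper-layer T/ET, %),
#'   wet-season soil moisture (vol %), and the herbivory ledger.
#' @slot types the strategy table used.
#' @slot config the [ScenarioConfig-class] that produced the run.
#' @export
setClass("RunSummary",
  representation(annual = "data.frame", types = "data.frame",
                 config = "ScenarioConfig"))

setMethod("show", "RunSummary", function(object) {
  a <- object@annual
  cat(sprintf(
    "RunSummary: %s at %g ha/LSU; %d replicates x %d years; mean total cover %.1f%%\n",
    object@config@landUse, object@config@stockingRate,
    length(unique(a$replicate)), max(a$year), mean(a$total_cover)))
})

#' @describeIn RunSummary-class the annual results table.
#' @param object a [RunSummary-class].
#' @export
annualTable <- function(object) object@annual

# Initial vegetation state: meta-PFT cover split equally among the meta's
# strategy types, uniform across cells.
.initVegState <- function(strategies, initCover, ncell) {
  cover <- matrix(0, ncell, nrow(strategies),
                  dimnames = list(NULL, strategies$id))
  for (m in unique(strategies$meta)) {
    idx <- which(strategies$meta == m)
    cover[, idx] <- initCover[[m]] / length(idx)
  }
  list(cover = cover, seedBank = cover)
}

# Growing-season day flags for one model year (October-April).
.growingSeasonFlags <- function() {
  .modelYearMonths() %in% c(10:12, 1:4)
}

#' Run a land-use scenario
#'
#' For every climate replicate: initialize the landscape, then per year run
#' daily hydrology (compiled core), biweekly vegetation dynamics within the
#' variable wet season, and herbivory plus mortality at the fixed end of
#' the growing season (30 April). RNG substreams are derived per replicate
#' from the master seed, so results are reproducible and replicate order
#' does not affect values.
#'
#' @param config a [ScenarioConfig-class].
#' @param climateSet list of [ClimateSeries-class], one per replicate,
#'   each covering at least `config@years` years.
#' @param verbose print per-replicate progress.
#' @return a [RunSummary-class].
#' @export
runScenario <- function(config, climateSet, verbose = FALSE) {
  validObject(config)
  if (length(climateSet) != config@replicates)
    stop("need one climate series per replicate")
  opts <- config@options
  strategies <- if (!is.null(opts$strategies)) opts$strategies
                else assembleStrategyTypes(config@landUse)
  staticTypes <- opts$staticTypes %||% character()
  vc <- opts$vegConstants %||% vegConstants()
  hc <- opts$hydroConstants %||% .hydroConstants()
  dem <- opts$dem %||% terrainGrid(0, cellSize = config@cellSize,
                                   nrow = config@gridRows,
                                   ncol = config@gridCols)
  nr <- config@gridRows; nc <- config@gridCols; ncell <- nr * nc
  areaHa <- scenarioArea(config)
  receiver <- .receiverIndex(dem)
  soilVec <- .soilVector(config@soil)
  groups <- .typeGroups(strategies)
  doyYear <- .calendarDoy(seq_len(365L))
  seasonFlags <- .growingSeasonFlags()
  seasonLength <- sum(seasonFlags)
  seasonEnd <- max(which(seasonFlags))    # 30 April
  dynamic <- !(strategies$id %in% staticTypes)

  rows <- vector("list", config@replicates)
  for (r in seq_len(config@replicates)) {
    clim <- climateSet[[r]]
    if (clim@years < config@years) stop("climate series shorter than run")
    # the RNG substream is keyed to the climate series (its generator seed)
    # when available, so permuting replicates permutes outputs unchanged
    key <- attr(clim, "seed")
    repSeed <- if (!is.null(key) && is.finite(key))
      as.integer((config@masterSeed + 131 * as.numeric(key)) %% 2147483629)
    else as.integer((config@masterSeed + 7919 * r) %% 2147483629)
    rows[[r]] <- .withSeed(repSeed, function()
      .runReplicate(config, clim, strategies, staticTypes, dynamic, vc, hc,
                    receiver, soilVec, groups, doyYear, seasonFlags,
                    seasonLength, seasonEnd, nr, nc, ncell, areaHa, r,
                    verbose))
  }
  annual <- do.call(rbind, rows)
  annual$scenario <- sprintf("%s_%g", config@landUse, config@stockingRate)
  new("RunSummary", annual = annual, types = strategies, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runReplicate <- function(config, clim, strategies, staticTypes, dynamic,
                          vc, hc, receiver, soilVec, groups, doyYear,
                          seasonFlags, seasonLength, seasonEnd, nr, nc,
                          ncell, areaHa, r, verbose) {
  veg <- .initVegState(strategies, config@initCover, ncell)
  thetaU <- rep(config@soil@fcUpper, ncell)
  thetaL <- rep(config@soil@fcLower, ncell)
  surface <- rep(0, ncell)
  effSr <- config@stockingRate
  bodyWeight <- config@options$bodyWeight %||% 450
  intakeFrac <- config@options$intakeFrac %||% 0.02
  out <- vector("list", config@years)
  uptakeRep <- rep(strategies$uptakeRate, each = ncell)
  coverCache <- NULL; totCache <- NULL   # invalidated on cover change
  diag <- isTRUE(config@options$diagnostics)
  diagRows <- vector("list", config@years)
  diagGrow <- numeric(nrow(strategies))

  for (y in seq_len(config@years)) {
    dayIdx <- ((y - 1L) * 365L + 1L):(y * 365L)
    precipY <- clim@precip[dayIdx]
    tempY <- clim@temp[dayIdx]
    bounds <- wetSeasonBounds(precipY)
    # segment boundaries: biweekly steps within the wet season, a split at
    # the fixed growing-season end for herbivory/mortality
    vegSteps <- integer()
    preSeason <- integer()
    if (!is.null(bounds)) {
      wsEnd <- min(bounds[["end"]], seasonEnd)
      starts <- seq(bounds[["start"]], wsEnd, by = 14L)
      vegSteps <- unique(pmin(c(starts[-1L] - 1L, wsEnd), wsEnd))
      preSeason <- bounds[["start"]] - 1L
    }
    cuts <- sort(unique(c(preSeason[preSeason >= 1L], vegSteps, seasonEnd,
                          365L)))
    segStart <- 1L
    evapY <- 0; transpY <- 0; transpUpY <- 0
    thetaUDailyY <- numeric(365L)
    stressG <- matrix(0L, ncell, length(groups$wp))

    for (segEnd in cuts) {
      if (segEnd < segStart) next
      seg <- segStart:segEnd
      if (is.null(coverCache)) {
        coverCache <- veg$cover * uptakeRep
        totCache <- rowSums(veg$cover)
      }
      h <- .hydroPeriod(thetaU, thetaL, surface, veg$cover, strategies,
                        groups, precipY[seg], tempY[seg], doyYear[seg],
                        seasonFlags[seg], receiver, soilVec, hc,
                        perType = segEnd %in% vegSteps,
                        coverUptake = coverCache, totCover = totCache)
      thetaU <- h$thetaU; thetaL <- h$thetaL; surface <- h$surface
      evapY <- evapY + sum(h$evapSum)
      transpY <- transpY + sum(h$transpSum)
      transpUpY <- transpUpY + sum(h$transpUpperSum)
      thetaUDailyY[seg] <- h$thetaUDaily
      stressG <- stressG + h$stressG

      if (segEnd %in% vegSteps) {
        pre <- colSums(veg$cover)
        veg <- stepBiweek(veg, h$transpType, h$thetaUCellSum / length(seg),
                          strategies, effSr, nr, nc, vc, staticTypes)
        if (diag) diagGrow <- diagGrow + (colSums(veg$cover) - pre)
        coverCache <- NULL
      }
      if (segEnd == seasonEnd) {
        # standing cover of the year: snapshot at the fixed growing-season
        # end, before biomass removal and die-back
        coverSnapshot <- colMeans(veg$cover) * 100
        preHerb <- colSums(veg$cover)
        # herbivory, then mortality, at the fixed growing-season end
        cfRain <- rainCorrection(sum(precipY), config@mapRef)
        hb <- applyHerbivory(veg$cover, strategies, config@stockingRate,
                             areaHa, cfRain, staticTypes, bodyWeight,
                             intakeFrac)
        veg$cover <- hb$cover
        stressFrac <- .clip(stressG / seasonLength, 0, 1)
        for (t in which(dynamic)) {
          veg$cover[, t] <- endSeasonMortality(
            veg$cover[, t], stressFrac[, groups$groupOf[t] + 1L],
            strategies[t, ], vc$b0)
        }
        # local extinction: cover below the quantum floor is cleared, and
        # annual seed banks decay between seasons
        veg$cover[veg$cover < vc$extinctCover] <- 0
        if (diag) {
          postHerb <- colSums(hb$cover)
          diagRows[[y]] <- data.frame(
            year = y, type = strategies$id, grow = diagGrow,
            herb = preHerb - postHerb, mort = postHerb - colSums(veg$cover),
            stress = colMeans(stressFrac)[groups$groupOf + 1L])
          diagGrow <- numeric(nrow(strategies))
        }
        ann <- strategies$meta == "annual"
        veg$seedBank[, ann] <- veg$seedBank[, ann] * vc$seedSurvival
        coverCache <- NULL
        effSr <- hb$outcome$effectiveSr
        yearOutcome <- hb$outcome
      }
      segStart <- segEnd + 1L
    }

    covMean <- coverSnapshot
    tUp <- transpUpY / ncell; tTot <- transpY / ncell; eTot <- evapY / ncell
    sm <- if (!is.null(bounds))
      mean(thetaUDailyY[bounds["start"]:bounds["end"]]) * 100 else NA_real_
    out[[y]] <- c(r, y, sum(covMean), tUp, tTot, eTot,
                  if (eTot + tUp > 0) 100 * tUp / (eTot + tUp) else 0,
                  sum(precipY), sm, yearOutcome$demand,
                  yearOutcome$removedTotal, yearOutcome$deficit,
                  yearOutcome$effectiveSr, covMean)
  }
  if (verbose) message(sprintf("replicate %d done", r))
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("replicate", "year", "total_cover", "transp_upper_mm",
                  "transp_mm", "evap_mm", "tet", "precip_mm",
                  "soil_moisture_volpct", "demand_kg", "removed_kg",
                  "deficit_kg", "effective_sr",
                  paste0("cover.", strategies$id))
  if (diag) attr(res, "diagnostics") <- do.call(rbind, diagRows)
  res
}

#' Summaries over the last 20 simulation years
#'
#' Means and standard deviations of every output variable over the last 20
#' years pooled across replicates, plus per-replicate means for downstream
#' statistics and per-type mean covers.
#'
#' @param summary a [RunSummary-class] (or its annual table).
#' @param lastYears number of final years to average (default 20).
#' @return list with `pooled` (data.frame variable/mean/sd),
#'   `perReplicate` (replicate x variable means) and `perType`
#'   (per-strategy mean cover %, pooled and per replicate).
#' @export
summarizeLast20 <- function(summary, lastYears = 20L) {
  a <- if (is(summary, "RunSummary")) summary@annual else summary
  if (max(a$year) < lastYears)
    stop(sprintf("need at least %d simulated years", lastYears))
  keep <- a[a$year > max(a$year) - lastYears, ]
  vars <- setdiff(names(keep), c("replicate", "year", "scenario"))
  num <- vars[vapply(keep[vars], is.numeric, logical(1L))]
  pooled <- data.frame(
    variable = num,
    mean = vapply(keep[num], function(x) mean(x, na.rm = TRUE), 0),
    sd = vapply(keep[num], function(x) sd(x, na.rm = TRUE), 0),
    row.names = NULL)
  perRep <- aggregate(keep[num], by = list(replicate = keep$replicate),
                      FUN = function(x) mean(x, na.rm = TRUE))
  coverCols <- grep("^cover\\.", num, value = TRUE)
  perType <- data.frame(
    id = sub("^cover\\.", "", coverCols),
    mean_cover_pct = vapply(keep[coverCols], mean, 0),
    row.names = NULL)
  list(pooled = pooled, perReplicate = perRep, perType = perType)
}
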