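# Configuration and file round-tripping: a single YAML configuration tree
# with sections climate/soil/vegetation/hydrology/scenario/analysis, plus
# tidy CSV output writers and a reproducibility manifest.

.configDefaults <- function() {
  list(
    climate = list(
      mapTarget = 291.3, pWetDay = 0.25, eventShape = 0.75, yearSdlog = 0.45,
      pDrySeason = 0, mat = 26, annualAmplitude = 5, dailySd = 1.5,
      coolestMonthMean = 19, warmestMonthMean = 29),
    soil = list(
      depthUpper = 200, depthLower = 800, porosity = 0.437, fcUpper = 0.125,
      fcLower = 0.125, residualWater = 0.035, soilWiltingPoint = 0.055,
      satConductivity = 1500, evaporationConstant = 0.16,
      diffusionCoeff = 0.05, textureLabel = "loamy sand"),
    vegetation = list(
      wue = 0.025, b0 = 0.25, pEst = 0.02, estMargin = 0.01,
      quantum = 0.002, kernelMean = 1, ldRate = 6, ldSeed = 5,
      seedSurvival = 1.0, extinctCover = 1e-4, pEstAnnual = 0.05,
      pEstShrub = 0.02, shrubSeedFactor = 0.1, annualSeedYield = 3,
      initShrub = 0.20, initPerennial = 0.20, initAnnual = 0.05),
    hydrology = list(
      infiltrationBare = 0.4, roughness = 0.8, shading = 0.85,
      stressThreshold = 0.25),
    scenario = list(
      landUse = "grazing", stockingRate = 40, years = 100L,
      replicates = 30L, gridRows = 30L, gridCols = 30L, cellSize = 5,
      masterSeed = 1L, bodyWeight = 450, intakeFrac = 0.02),
    analysis = list(thresholdPct = 2.5, lastYears = 20L)
  )
}

.validateConfigSection <- function(given, defaults, section) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s' in section '%s'",
                 unknown[1L], section), call. = FALSE)
  merged <- utils::modifyList(defaults, given)
  merged
}

.validateConfigValues <- function(cfg) {
  ck <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  ck(cfg$climate$pWetDay >= 0 && cfg$climate$pWetDay <= 1,
     "climate: pWetDay must lie in [0, 1]")
  ck(cfg$climate$mapTarget > 0, "climate: mapTarget must be positive")
  ck(cfg$scenario$stockingRate > 0,
     "scenario: stockingRate must be positive")
  ck(cfg$scenario$landUse %in% c("grazing", "browsing"),
     "scenario: landUse must be 'grazing' or 'browsing'")
  ck(cfg$scenario$years >= 1, "scenario: years must be >= 1")
  ck(cfg$vegetation$wue >= 0, "vegetation: wue must be non-negative")
  ck(cfg$soil$porosity > cfg$soil$fcUpper,
     "soil: porosity must exceed field capacity")
  invisible(cfg)
}

#' Load and validate a YAML configuration
#'
#' Reads a configuration tree with sections `climate`, `soil`,
#' `vegetation`, `hydrology`, `scenario` and `analysis`; unknown keys are
#' rejected with a message naming the key, missing keys receive documented
#' defaults, and cross-field constraints are checked.
#'
#' @param path YAML file; `NULL` returns the pure defaults.
#' @return validated configuration list (class `savannaConfig`).
#' @export
loadConfig <- function(path = NULL) {
  given <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- .configDefaults()
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration section '%s'", unknown[1L]),
         call. = FALSE)
  cfg <- lapply(names(defaults), function(s)
    .validateConfigSection(given[[s]] %||% list(), defaults[[s]], s))
  names(cfg) <- names(defaults)
  cfg$scenario$years <- as.integer(cfg$scenario$years)
  cfg$scenario$replicates <- as.integer(cfg$scenario$replicates)
  .validateConfigValues(cfg)
  structure(cfg, class = "savannaConfig")
}

#' @rdname loadConfig
#' @param config a `savannaConfig` list.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param config a `savannaConfig` from [loadConfig()].
#' @return list with `climate` ([ClimateConfig-class]), `soil`
#'   ([SoilParams-class]) and `scenario` ([ScenarioConfig-class]).
#' @export
buildFromConfig <- function(config) {
  stopifnot(inherits(config, "savannaConfig"))
  cc <- do.call(climateConfig, config$climate)
  soil <- do.call(soilParams, config$soil)
  v <- config$vegetation
  vegc <- vegConstants(v$wue, v$b0, v$pEst, v$estMargin, v$quantum,
                       v$kernelMean, v$ldRate, v$ldSeed, v$seedSurvival,
                       v$extinctCover, v$pEstAnnual, v$pEstShrub,
                       v$shrubSeedFactor, v$annualSeedYield)
  h <- config$hydrology
  s <- config$scenario
  sc <- scenarioConfig(
    landUse = s$landUse, stockingRate = s$stockingRate, years = s$years,
    replicates = s$replicates, gridRows = s$gridRows, gridCols = s$gridCols,
    cellSize = s$cellSize,
    initCover = c(shrub = v$initShrub, perennial = v$initPerennial,
                  annual = v$initAnnual),
    masterSeed = s$masterSeed, mapRef = config$climate$mapTarget,
    soil = soil, vegConstants = vegc,
    hydroConstants = .hydroConstants(h$infiltrationBare, h$roughness,
                                     h$shading, h$stressThreshold),
    bodyWeight = s$bodyWeight, intakeFrac = s$intakeFrac)
  list(climate = cc, soil = soil, scenario = sc)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical YAML serialization; changes iff the
#' configuration changes.
#'
#' @param config a `savannaConfig`.
#' @return hex digest string.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  saveConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write scenario outputs as tidy CSV plus a run manifest
#'
#' Writes `annual.csv` (full annual table, stable column order),
#' `cover_by_type.csv` (long per-type cover), `herbivory.csv` (the yearly
#' herbivory ledger) and `manifest.json` (config hash, master seed,
#' package version, creation time).
#'
#' @param summary a [RunSummary-class].
#' @param dir output directory (created if needed).
#' @param config optional `savannaConfig` recorded in the manifest.
#' @return invisible character vector of the written paths.
#' @export
writeOutputs <- function(summary, dir, config = loadConfig()) {
  stopifnot(is(summary, "RunSummary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- summary@annual
  lead <- c("scenario", "replicate", "year")
  a <- a[, c(intersect(lead, names(a)), sort(setdiff(names(a), lead)))]
  pAnnual <- file.path(dir, "annual.csv")
  write.csv(a, pAnnual, row.names = FALSE)

  coverCols <- grep("^cover\\.", names(a), value = TRUE)
  long <- do.call(rbind, lapply(coverCols, function(cc)
    data.frame(scenario = a$scenario, replicate = a$replicate,
               year = a$year, strategy_id = sub("^cover\\.", "", cc),
               mean_cover_pct = a[[cc]])))
  if (is.null(long))
    long <- data.frame(scenario = character(), replicate = integer(),
                       year = integer(), strategy_id = character(),
                       mean_cover_pct = numeric())
  pCover <- file.path(dir, "cover_by_type.csv")
  write.csv(long[order(long$replicate, long$year, long$strategy_id), ],
            pCover, row.names = FALSE)

  ledger <- a[, intersect(c("scenario", "replicate", "year", "demand_kg",
                            "removed_kg", "deficit_kg", "effective_sr"),
                          names(a))]
  pLedger <- file.path(dir, "herbivory.csv")
  write.csv(ledger, pLedger, row.names = FALSE)

  manifest <- list(
    configHash = configHash(config),
    masterSeed = summary@config@masterSeed,
    scenario = sprintf("%s_%g", summary@config@landUse,
                       summary@config@stockingRate),
    packageVersion = as.character(utils::packageVersion("savannaSim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  pManifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, pManifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(pAnnual, pCover, pLedger, pManifest))
}
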