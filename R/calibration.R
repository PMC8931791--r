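# Trait sensitivity scans and the regression solve that turns a +-10% cover
# deviation target into a trait value. These scans generated the shipped
# trade-off table (strategyTraitTable()); they remain runnable so the
# parameterization is reproducible end to end.

.SCANNABLE <- c("tVeg", "mrd", "herbivorePref", "defense", "uptakeRate",
                "wiltingPoint")

#' Sensitivity community for a trait scan
#'
#' The altered type and the base type of the focal meta-PFT (both with
#' dynamic cover) plus the base types of the other two meta-PFTs with
#' static (frozen) cover, following the calibration design: performance is
#' assessed in a simple community at medium animal density.
#'
#' @param landUse `"grazing"` or `"browsing"`.
#' @param meta `"perennial"` or `"shrub"`: the focal meta-PFT.
#' @param parameter one of the six trait names.
#' @param value trait value of the altered type.
#' @return list with `strategies` (4-row table; the altered type has id
#'   `<prefix>.alt`) and `staticTypes`.
#' @export
sensitivityCommunity <- function(landUse, meta, parameter, value) {
  if (!parameter %in% .SCANNABLE)
    stop(sprintf("unknown parameter '%s'", parameter))
  all <- assembleStrategyTypes(landUse)
  bases <- all[all$code == "base", ]
  focalBase <- bases[bases$meta == meta, ]
  altered <- focalBase
  altered[[parameter]] <- value
  prefix <- strsplit(focalBase$id, ".", fixed = TRUE)[[1L]][1L]
  altered$id <- paste0(prefix, ".alt")
  altered$code <- "alt"
  community <- rbind(altered, bases)
  rownames(community) <- community$id
  list(strategies = community,
       staticTypes = bases$id[bases$meta != meta])
}

#' Scan one trait over a relative range
#'
#' Runs the sensitivity community for `nPoints` equally spaced settings of
#' the trait within `+-relRange` of its default, records the altered type's
#' mean cover over the final years of each run, and fits a pooled linear
#' regression of cover on the trait value.
#'
#' @param landUse,meta focal land use and meta-PFT.
#' @param parameter one of the six trait names.
#' @param climateSet list of [ClimateSeries-class], one per replicate.
#' @param relRange half-width of the scan as a fraction of the default.
#' @param nPoints number of settings (>= 3, default 7).
#' @param years,lastYears run length and averaging window.
#' @param stockingRate animal density of the scan (medium, 40 ha/LSU).
#' @param masterSeed seed for the simulation RNG substreams.
#' @param coverFun optional stub `function(value) -> mean cover` replacing
#'   the simulation (used to validate the regression machinery).
#' @return object of class `scanResult`: list with `parameter`, `values`,
#'   `meanCover`, `baseValue`, `baseCover`, `slope`, `intercept`, `slopeP`.
#' @export
scanParameter <- function(landUse, meta, parameter, climateSet,
                          relRange = 0.30, nPoints = 7L, years = 100L,
                          lastYears = 20L, stockingRate = 40,
                          masterSeed = 1L, coverFun = NULL) {
  if (!parameter %in% .SCANNABLE)
    stop(sprintf("unknown parameter '%s'", parameter))
  if (nPoints < 3L) stop("need at least 3 scan points")
  if (relRange <= 0) stop("need a positive scan range (>= 2 distinct values)")
  base <- assembleStrategyTypes(landUse)
  default <- base[base$code == "base" & base$meta == meta, parameter]
  values <- default * seq(1 - relRange, 1 + relRange, length.out = nPoints)
  meanCover <- numeric(nPoints)
  for (k in seq_len(nPoints)) {
    if (!is.null(coverFun)) {
      meanCover[k] <- coverFun(values[k])
      next
    }
    comm <- sensitivityCommunity(landUse, meta, parameter, values[k])
    cfg <- scenarioConfig(landUse, stockingRate = stockingRate,
                          years = years,
                          replicates = length(climateSet),
                          masterSeed = masterSeed,
                          strategies = comm$strategies,
                          staticTypes = comm$staticTypes)
    rs <- runScenario(cfg, climateSet)
    s20 <- summarizeLast20(rs, lastYears)
    altId <- grep("\\.alt$", s20$perType$id, value = TRUE)
    meanCover[k] <- s20$perType$mean_cover_pct[s20$perType$id == altId]
  }
  fit <- lm(meanCover ~ values)
  # an exactly linear response (stub oracles) triggers the perfect-fit note
  ct <- suppressWarnings(summary(fit)$coefficients)
  iBase <- which.min(abs(values - default))
  structure(list(parameter = parameter, landUse = landUse, meta = meta,
                 values = values, meanCover = meanCover,
                 baseValue = default, baseCover = meanCover[iBase],
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 slopeP = if (nrow(ct) > 1L) ct[2L, 4L] else NA_real_),
            class = "scanResult")
}

#' @export
print.scanResult <- function(x, ...) {
  cat(sprintf(
    "Trait scan %s (%s %s): slope %.4g (p = %.3g), base cover %.2f%%\n",
    x$parameter, x$landUse, x$meta, x$slope, x$slopeP, x$baseCover))
  invisible(x)
}

#' Solve a trait value for a target cover deviation
#'
#' Inverts the scan regression: the trait value predicted to change the
#' base type's cover by `target` (e.g. +10%). Parameters whose slope is not
#' significant are excluded from strategy parameterization.
#'
#' @param scan a `scanResult` from [scanParameter()].
#' @param baseCover reference cover (%); defaults to the scan's own base
#'   cover.
#' @param target relative cover deviation (default +0.10).
#' @param alpha significance level for the slope (default 0.05).
#' @return the trait value, or the string `"excluded"` when the slope is
#'   not significant.
#' @export
solveTargetDeviation <- function(scan, baseCover = scan$baseCover,
                                 target = 0.10, alpha = 0.05) {
  stopifnot(inherits(scan, "scanResult"))
  if (target == 0) return(scan$baseValue)
  if (is.na(scan$slopeP) || scan$slopeP >= alpha) return("excluded")
  if (scan$slope == 0) stop("degenerate scan: zero slope with significant p")
  (baseCover * (1 + target) - scan$intercept) / scan$slope
}
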