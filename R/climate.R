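# Stochastic daily weather generator for a semi-arid savanna site.
#
# Rainfall: wet days occur as independent Bernoulli trials within the wet
# season (October-April); event depths are gamma distributed. A yearly
# log-normal wetness multiplier (mean 1) scales event depths so that annual
# sums reproduce the strong interannual variability of the site while the
# long-run mean stays at the configured mean annual precipitation.
# Temperature: a time-warped seasonal curve (minimum mid-June, maximum
# mid-October) plus i.i.d. Gaussian daily noise.

#' Climate generator configuration
#'
#' @slot mapTarget target mean annual precipitation (mm/yr).
#' @slot wetSeasonMonths integer months (1-12) in which rain can fall.
#' @slot pWetDay probability that a wet-season day receives rain.
#' @slot eventMean mean depth (mm) of a rain event in an average year.
#' @slot eventShape gamma shape of event depths (dimensionless).
#' @slot yearSdlog log-sd of the yearly wetness multiplier (dimensionless).
#' @slot pDrySeason probability of a (drizzle) event outside the wet season.
#' @slot mat mean annual temperature (degC).
#' @slot annualAmplitude half-range of the seasonal temperature cycle (degC).
#' @slot dailySd sd of daily temperature noise (degC).
#' @slot coolestMonthMean June monthly mean temperature (degC).
#' @slot warmestMonthMean October monthly mean temperature (degC).
#' @export
setClass("ClimateConfig",
  representation(
    mapTarget = "numeric", wetSeasonMonths = "integer", pWetDay = "numeric",
    eventMean = "numeric", eventShape = "numeric", yearSdlog = "numeric",
    pDrySeason = "numeric", mat = "numeric", annualAmplitude = "numeric",
    dailySd = "numeric", coolestMonthMean = "numeric",
    warmestMonthMean = "numeric"
  )
)

setValidity("ClimateConfig", function(object) {
  msg <- character()
  if (object@pWetDay < 0 || object@pWetDay > 1)
    msg <- c(msg, "pWetDay must lie in [0, 1]")
  if (object@pDrySeason < 0 || object@pDrySeason > 1)
    msg <- c(msg, "pDrySeason must lie in [0, 1]")
  if (object@eventMean <= 0) msg <- c(msg, "eventMean must be positive")
  if (object@eventShape <= 0) msg <- c(msg, "eventShape must be positive")
  if (object@dailySd < 0) msg <- c(msg, "dailySd must be non-negative")
  if (object@pWetDay > 0) {
    expected <- object@pWetDay * .daysInMonths(object@wetSeasonMonths) *
      object@eventMean
    if (abs(expected - object@mapTarget) > 0.01 * object@mapTarget)
      msg <- c(msg, sprintf(
        "expected annual sum %.1f mm deviates more than 1%% from mapTarget %.1f mm",
        expected, object@mapTarget))
  }
  if (length(msg)) msg else TRUE
})

#' Create a climate generator configuration
#'
#' Defaults describe the study site: mean annual precipitation 291.3 mm
#' falling October-April, mean annual temperature 26 degC with a June minimum
#' of 19 degC and an October maximum of 29 degC. When `eventMean` is omitted
#' it is derived from `mapTarget`, `pWetDay` and the length of the wet season
#' so that the expected annual sum equals `mapTarget` exactly.
#'
#' @param mapTarget mean annual precipitation target (mm/yr).
#' @param wetSeasonMonths months in which rain can occur (default Oct-Apr).
#' @param pWetDay per-day rain probability within the wet season.
#' @param eventMean mean event depth (mm); derived from `mapTarget` if `NULL`.
#' @param eventShape gamma shape of event depths.
#' @param yearSdlog log-sd of the yearly wetness multiplier; 0 disables
#'   interannual variability beyond day-to-day sampling.
#' @param pDrySeason probability of rain on a dry-season day (default 0).
#' @param mat mean annual temperature (degC).
#' @param annualAmplitude half-range of the seasonal cycle (degC).
#' @param dailySd sd of daily temperature noise (degC).
#' @param coolestMonthMean,warmestMonthMean June and October monthly means.
#' @return A validated [ClimateConfig-class] object.
#' @examples
#' cfg <- climateConfig()
#' cfg@eventMean * cfg@pWetDay * 212  # expected annual sum = mapTarget
#' @export
climateConfig <- function(mapTarget = 291.3,
                          wetSeasonMonths = c(10:12, 1:4),
                          pWetDay = 0.25,
                          eventMean = NULL,
                          eventShape = 0.75,
                          yearSdlog = 0.45,
                          pDrySeason = 0,
                          mat = 26,
                          annualAmplitude = 5,
                          dailySd = 1.5,
                          coolestMonthMean = 19,
                          warmestMonthMean = 29) {
  .assertScalarNumeric(mapTarget, "mapTarget", lo = 0)
  .assertScalarNumeric(pWetDay, "pWetDay", lo = 0, hi = 1)
  wetSeasonMonths <- as.integer(wetSeasonMonths)
  if (is.null(eventMean)) {
    nWet <- .daysInMonths(wetSeasonMonths)
    eventMean <- if (pWetDay > 0 && nWet > 0) mapTarget / (pWetDay * nWet) else 1
  }
  new("ClimateConfig",
    mapTarget = mapTarget, wetSeasonMonths = wetSeasonMonths,
    pWetDay = pWetDay, eventMean = eventMean, eventShape = eventShape,
    yearSdlog = yearSdlog, pDrySeason = pDrySeason, mat = mat,
    annualAmplitude = annualAmplitude, dailySd = dailySd,
    coolestMonthMean = coolestMonthMean, warmestMonthMean = warmestMonthMean)
}

#' Daily climate series
#'
#' Daily precipitation (mm) and mean temperature (degC) over `years` model
#' years of 365 days each. Model years start on 1 July so the October-April
#' wet season is never split across year boundaries.
#'
#' @slot precip daily precipitation, mm/day.
#' @slot temp daily mean temperature, degC.
#' @slot years number of simulated years.
#' @export
setClass("ClimateSeries",
  representation(precip = "numeric", temp = "numeric", years = "integer"))

setValidity("ClimateSeries", function(object) {
  msg <- character()
  n <- 365L * object@years
  if (length(object@precip) != n)
    msg <- c(msg, sprintf("precip must have length 365 x years = %d", n))
  if (length(object@temp) != n)
    msg <- c(msg, "temp and precip must have equal length")
  if (any(object@precip < 0)) msg <- c(msg, "precip must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClimateSeries-class construct a climate series from daily
#'   vectors.
#' @param precip,temp daily series of equal length `365 * years`.
#' @param years integer number of model years.
#' @export
climateSeries <- function(precip, temp, years = length(precip) %/% 365L) {
  new("ClimateSeries", precip = as.numeric(precip), temp = as.numeric(temp),
      years = as.integer(years))
}

setMethod("show", "ClimateSeries", function(object) {
  sums <- annualPrecip(object)
  cat(sprintf(
    "ClimateSeries: %d years; annual precip mean %.1f mm (range %.1f-%.1f); mean temp %.1f degC\n",
    object@years, mean(sums), min(sums), max(sums), mean(object@temp)))
})

#' Annual precipitation sums of a climate series
#' @param series a [ClimateSeries-class].
#' @return numeric vector of length `years` with mm per model year.
#' @export
annualPrecip <- function(series) {
  stopifnot(is(series, "ClimateSeries"))
  as.numeric(tapply(series@precip,
                    rep(seq_len(series@years), each = 365L), sum))
}

#' Generate a stochastic daily precipitation series
#'
#' Wet-season days (by default October-April) receive rain with probability
#' `pWetDay`; event depths are gamma distributed with mean
#' `eventMean x yearly wetness multiplier`. Identical `(config, years, seed)`
#' yields a bit-identical series.
#'
#' @param config a [ClimateConfig-class].
#' @param years number of model years (>= 1).
#' @param seed integer RNG seed.
#' @return numeric vector of daily precipitation, length `365 * years`.
#' @export
generatePrecipitation <- function(config, years, seed) {
  stopifnot(is(config, "ClimateConfig"))
  validObject(config)
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("'years' must be a positive integer")
  months <- .modelYearMonths()
  inSeason <- months %in% config@wetSeasonMonths
  pDay <- ifelse(inSeason, config@pWetDay, config@pDrySeason)
  .withSeed(seed, function() {
    precip <- numeric(365L * years)
    for (y in seq_len(years)) {
      f <- if (config@yearSdlog > 0)
        rlnorm(1L, meanlog = -config@yearSdlog^2 / 2, sdlog = config@yearSdlog)
      else 1
      wet <- runif(365L) < pDay
      nWet <- sum(wet)
      depths <- if (nWet > 0L)
        rgamma(nWet, shape = config@eventShape,
               scale = f * config@eventMean / config@eventShape)
      else numeric()
      dayIdx <- (y - 1L) * 365L + which(wet)
      precip[dayIdx] <- depths
      precip
    }
    precip
  })
}

# Seasonal temperature curve: a time-warped cosine with minimum at mid-June
# and maximum at mid-October, plus a quadratic term that lets the annual mean
# sit asymmetrically between the two extremes.
.seasonalTemp <- function(calendarDoy, mat, coolest, warmest, amplitude) {
  doyJun <- 166  # 15 June
  doyOct <- 288  # 15 October
  rise <- doyOct - doyJun            # 122 days June -> October
  fall <- 365 - rise                 # 243 days October -> June
  phi <- ifelse(calendarDoy > doyJun & calendarDoy <= doyOct,
                pi + pi * (calendarDoy - doyJun) / rise,
                pi * (((calendarDoy - doyOct) %% 365) / fall))
  s <- cos(phi)
  mid <- (coolest + warmest) / 2
  c1 <- (warmest - coolest) / 2
  c2 <- 2 * (mid - mat)
  c0 <- 2 * mat - mid
  base <- c0 + c1 * s + c2 * s^2
  ampDefault <- c1
  if (ampDefault == 0) return(rep(mat, length(calendarDoy)))
  mat + (amplitude / ampDefault) * (base - mat)
}

#' Generate a stochastic daily temperature series
#'
#' Daily means follow a seasonal curve through the coolest (June) and warmest
#' (October) monthly means with overall mean equal to `mat`, plus independent
#' Gaussian daily noise of sd `dailySd`.
#'
#' @inheritParams generatePrecipitation
#' @return numeric vector of daily mean temperature, length `365 * years`.
#' @export
generateTemperature <- function(config, years, seed) {
  stopifnot(is(config, "ClimateConfig"))
  if (config@dailySd < 0) stop("dailySd must be non-negative")
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("'years' must be a positive integer")
  doy <- .calendarDoy(seq_len(365L))
  seasonal <- .seasonalTemp(doy, config@mat, config@coolestMonthMean,
                            config@warmestMonthMean, config@annualAmplitude)
  n <- 365L * years
  .withSeed(seed, function() {
    rep(seasonal, years) + if (config@dailySd > 0) rnorm(n, 0, config@dailySd)
                           else 0
  })
}

#' Generate a full daily climate series
#'
#' Convenience wrapper combining [generatePrecipitation()] and
#' [generateTemperature()] on decoupled seeds derived from `seed`.
#'
#' @inheritParams generatePrecipitation
#' @return a [ClimateSeries-class].
#' @export
generateClimate <- function(config, years, seed) {
  out <- climateSeries(
    generatePrecipitation(config, years, seed),
    generateTemperature(config, years, seed + 500000L),
    years
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Start and end of the variable wet season
#'
#' The wet season of a hydrological year (1 July-30 June) runs from the first
#' to the last day with a rain event of at least `threshold` mm/day
#' (inclusive).
#'
#' @param precipYear daily precipitation of one model year (length 365).
#' @param threshold event threshold in mm/day (default 5).
#' @return integer vector `c(start, end)` of day indices within the year, or
#'   `NULL` when no qualifying event occurs.
#' @export
wetSeasonBounds <- function(precipYear, threshold = 5) {
  if (length(precipYear) == 0L) stop("empty precipitation series")
  qual <- which(precipYear >= threshold)
  if (length(qual) == 0L) return(NULL)
  c(start = qual[1L], end = qual[length(qual)])
}

#' Scale a precipitation series by a calibration factor
#'
#' Multiplies every daily value by `factor`; annual sums scale exactly by the
#' same factor. Used to correct satellite-derived rainfall against rain-gauge
#' records.
#'
#' @param series numeric daily series (mm/day).
#' @param factor positive multiplier (default 1.16).
#' @return the scaled series.
#' @export
applyCalibrationFactor <- function(series, factor = 1.16) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("'factor' must be a positive number")
  series * factor
}

#' Write / read a climate series as CSV
#'
#' One file per replicate with columns `date` (ISO-8601), `precip_mm`,
#' `temp_c`, preceded by a comment line recording the replicate index and
#' seed.
#'
#' @param series a [ClimateSeries-class].
#' @param path output file path.
#' @param replicate integer replicate index recorded in the header.
#' @param seed integer seed recorded in the header.
#' @export
writeClimateCsv <- function(series, path, replicate = 1L, seed = NA_integer_) {
  stopifnot(is(series, "ClimateSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# replicate=%d seed=%s", as.integer(replicate),
                     as.character(seed)), con)
  df <- data.frame(date = .modelDayDates(length(series@precip)),
                   precip_mm = series@precip, temp_c = series@temp)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' @rdname writeClimateCsv
#' @return `readClimateCsv` returns a [ClimateSeries-class] with attributes
#'   `replicate` and `seed` from the header comment.
#' @export
readClimateCsv <- function(path) {
  header <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#")
  out <- climateSeries(df$precip_mm, df$temp_c)
  m <- regmatches(header, regexec("replicate=(\\d+) seed=(\\S+)", header))[[1L]]
  if (length(m) == 3L) {
    attr(out, "replicate") <- as.integer(m[2L])
    attr(out, "seed") <- suppressWarnings(as.integer(m[3L]))
  }
  out
}
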