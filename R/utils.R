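# Internal helpers: seeded evaluation, the 365-day model calendar, clipping.

# Evaluate `fun()` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  fun()
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# The model year has 365 days and starts on 1 July so that a single wet season
# (October-April) is never split across years. Day 1 = 1 July.
.DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_END_DOY <- cumsum(.DAYS_IN_MONTH)
.MODEL_YEAR_OFFSET <- 181L  # calendar doy of 30 June

# Calendar day-of-year (1 = 1 Jan) for a day index within the model year.
.calendarDoy <- function(modelDay) {
  ((as.integer(modelDay) - 1L + .MODEL_YEAR_OFFSET) %% 365L) + 1L
}

# Calendar month (1-12) for a calendar day-of-year.
.doyMonth <- function(doy) {
  findInterval(doy - 1L, c(0L, .MONTH_END_DOY[-12L])) |>
    as.integer()
}

# Month of each of the 365 model-year days (day 1 = 1 July).
.modelYearMonths <- function() .doyMonth(.calendarDoy(seq_len(365L)))

# Number of days per model year falling in the given set of months.
.daysInMonths <- function(months) sum(.modelYearMonths() %in% months)

# "YYYY-MM-DD" labels for a series of model days, with model year 1 starting
# 1 July of `baseYear`.
.modelDayDates <- function(n, baseYear = 2000L) {
  day <- seq_len(n)
  yearIdx <- (day - 1L) %/% 365L
  doy <- .calendarDoy(((day - 1L) %% 365L) + 1L)
  mo <- .doyMonth(doy)
  dom <- doy - c(0L, .MONTH_END_DOY)[mo]
  calYear <- baseYear + yearIdx + ifelse(doy <= .MODEL_YEAR_OFFSET, 1L, 0L)
  sprintf("%04d-%02d-%02d", calYear, mo, dom)
}

.assertScalarNumeric <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
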