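# Stochastic weather generator: determinism, seasonality, long-run
# statistics, wet-season bounds and the gauge calibration factor.

test_that("identical seed and config give bit-identical series", {
  cfg <- climateConfig()
  expect_identical(generatePrecipitation(cfg, 3, 42),
                   generatePrecipitation(cfg, 3, 42))
  expect_identical(generateTemperature(cfg, 3, 42),
                   generateTemperature(cfg, 3, 42))
  expect_false(identical(generatePrecipitation(cfg, 3, 42),
                         generatePrecipitation(cfg, 3, 43)))
})

test_that("degenerate probabilities and inputs are handled", {
  cfg <- climateConfig(pWetDay = 0, eventMean = 1)
  expect_true(all(generatePrecipitation(cfg, 2, 1) == 0))
  expect_error(generatePrecipitation(climateConfig(), 0, 1), "years")
  flat <- climateConfig(annualAmplitude = 0, dailySd = 0)
  expect_equal(unique(generateTemperature(flat, 1, 1)), flat@mat)
})

test_that("rain falls only in wet-season months by default", {
  p <- generatePrecipitation(climateConfig(), 10, 7)
  months <- rep(savannaSim:::.modelYearMonths(), 10)
  expect_true(all(p[!months %in% c(10:12, 1:4)] == 0))
  expect_gt(sum(p[months %in% c(10:12, 1:4)]), 0)
})

test_that("long-run precipitation statistics match the configuration", {
  cfg <- climateConfig()
  sums <- unlist(lapply(1:30, function(r)
    annualPrecip(climateSeries(generatePrecipitation(cfg, 100, 1000 + r),
                               numeric(36500)))))
  # mean annual sum within 5% of the target over 3000 simulated years
  expect_lt(abs(mean(sums) - cfg@mapTarget) / cfg@mapTarget, 0.05)
  # interannual spread covers the observed range of annual sums
  expect_lt(min(sums), 60)
  expect_gt(max(sums), 700)
})

test_that("mean annual precipitation converges with more replicates", {
  cfg <- climateConfig()
  m <- function(reps) mean(unlist(lapply(seq_len(reps), function(r)
    annualPrecip(climateSeries(generatePrecipitation(cfg, 30, 400 + r),
                               numeric(30 * 365))))))
  errSmall <- abs(m(5) - cfg@mapTarget)
  errLarge <- abs(m(15) - cfg@mapTarget)
  expect_lt(errLarge, errSmall + 5)  # no divergence at 3x replicates
  expect_lt(errLarge / cfg@mapTarget, 0.06)
})

test_that("temperature hits the June, October and annual means", {
  tmp <- generateTemperature(climateConfig(), 100, 7)
  months <- rep(savannaSim:::.modelYearMonths(), 100)
  expect_lt(abs(mean(tmp) - 26), 0.3)
  expect_lt(abs(mean(tmp[months == 6]) - 19), 0.6)
  expect_lt(abs(mean(tmp[months == 10]) - 29), 0.6)
  # daily noise magnitude
  cfg0 <- climateConfig(dailySd = 0)
  noise <- tmp - generateTemperature(cfg0, 100, 99)
  expect_lt(abs(sd(noise) - 1.5), 0.1)
})

test_that("wet-season bounds follow the 5 mm/day inclusive threshold", {
  y <- numeric(365)
  y[100] <- 6; y[200] <- 10; y[150] <- 4.9
  expect_equal(unname(wetSeasonBounds(y)), c(100, 200))
  expect_null(wetSeasonBounds(rep(4.99, 365)))
  single <- numeric(365); single[77] <- 5.0
  expect_equal(unname(wetSeasonBounds(single)), c(77, 77))
  expect_error(wetSeasonBounds(numeric()), "empty")
})

test_that("calibration factor scales series exactly", {
  y <- c(0, 10, 250 - 10, 0)
  expect_identical(applyCalibrationFactor(y, 1), y)
  expect_equal(sum(applyCalibrationFactor(y, 1.16)), 290)
  expect_true(all(applyCalibrationFactor(numeric(10), 1.16) == 0))
  expect_error(applyCalibrationFactor(y, 0), "positive")
})

test_that("climate CSV round-trips with replicate metadata", {
  s <- tinyClimate(years = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  writeClimateCsv(s, path, replicate = 4L, seed = 3L)
  back <- readClimateCsv(path)
  expect_equal(back@precip, s@precip, tolerance = 1e-12)
  expect_equal(back@temp, s@temp, tolerance = 1e-12)
  expect_identical(attr(back, "replicate"), 4L)
  expect_identical(attr(back, "seed"), 3L)
  unlink(path)
})
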