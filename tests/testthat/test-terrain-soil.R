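# DEM interpolation and I/O; soil parameter validity and the RMSE-based
# calibration harness.

test_that("bilinear DEM interpolation preserves constants, linear fields and corners", {
  const <- terrainGrid(1195, cellSize = 30, nrow = 3L, ncol = 3L)
  fine <- interpolateDem(const, 5)
  expect_true(all(fine@elevation == 1195))
  expect_equal(fine@cellSize, 5)

  ramp <- terrainGrid(matrix(rep(seq(0, 20, by = 10), each = 3), 3, 3),
                      cellSize = 30)
  fineR <- interpolateDem(ramp, 10)
  # a linear field is reproduced exactly at the fine nodes
  expect_equal(fineR@elevation[1, ], seq(0, 20, length.out = 7))

  z <- terrainGrid(matrix(c(0, 6, 6, 12), 2, 2), cellSize = 30)
  f <- interpolateDem(z, 5)
  # hand-evaluated bilinear closed form: z(u, v) = 6u + 6v on [0,1]^2
  u <- seq(0, 1, length.out = 7)
  expect_equal(f@elevation, outer(u, u, function(a, b) 6 * a + 6 * b))
  expect_equal(f@elevation[c(1, 7), c(1, 7)], z@elevation)  # corners
  expect_error(interpolateDem(z, 7), "divide")
})

test_that("DEM files round-trip through ASCII grid and CSV", {
  dem <- slopedDem(4, 3)
  asc <- tempfile(fileext = ".asc")
  writeDemAsc(dem, asc)
  expect_equal(readDemAsc(asc)@elevation, dem@elevation)
  expect_equal(readDemAsc(asc)@cellSize, dem@cellSize)
  csv <- tempfile(fileext = ".csv")
  writeDemCsv(dem, csv)
  expect_equal(readDemCsv(csv, cellSize = 5)@elevation, dem@elevation)
  unlink(c(asc, csv))
})

test_that("soil parameter invariants are enforced", {
  expect_error(soilParams(residualWater = 0.06),
               "residualWater < soilWiltingPoint")
  expect_error(soilParams(porosity = 0.12), "fieldCapacity < porosity")
  expect_error(soilParams(diffusionCoeff = -1), "diffusionCoeff")
  expect_s4_class(soilParams(), "SoilParams")
})

test_that("soil calibration recovers known parameters", {
  clim <- tinyClimate(years = 2, seed = 21)
  truth <- soilParams(evaporationConstant = 0.16)
  obs <- simulateSoilMoisture(truth, clim)
  grid <- data.frame(evaporationConstant = c(0.06, 0.11, 0.16, 0.21, 0.26))

  # exact self-consistency: the true parameters give RMSE 0
  fit <- calibrateSoil(obs, grid, clim)
  expect_equal(fit$soil@evaporationConstant, 0.16)
  expect_equal(fit$rmse, 0)

  # RMSE equals an independently recomputed root mean square deviation
  simBest <- simulateSoilMoisture(fit$soil, clim)
  rmseManual <- sqrt(mean(c(simBest$thetaUpper - obs$thetaUpper,
                            simBest$thetaLower - obs$thetaLower)^2))
  expect_equal(fit$rmse, rmseManual, tolerance = 1e-12)

  # parameter recovery under observation noise, within one grid step
  set.seed(7)
  noisy <- obs + matrix(rnorm(2 * nrow(obs), 0, 0.005), ncol = 2)
  fitN <- calibrateSoil(noisy, grid, clim)
  expect_lte(abs(fitN$soil@evaporationConstant - 0.16), 0.05)

  expect_error(calibrateSoil(obs[0, ], grid, clim), "empty")
  expect_error(calibrateSoil(obs, grid[0, , drop = FALSE], clim), "empty")
  expect_error(calibrateSoil(obs[1:10, ], grid, clim), "same days")
})

test_that("calibration result does not depend on candidate order", {
  clim <- tinyClimate(years = 1, seed = 22)
  truth <- soilParams()
  obs <- simulateSoilMoisture(truth, clim)
  grid <- data.frame(evaporationConstant = c(0.05, 0.16, 0.3))
  a <- calibrateSoil(obs, grid, clim)
  b <- calibrateSoil(obs, grid[3:1, , drop = FALSE], clim)
  expect_equal(a$soil@evaporationConstant, b$soil@evaporationConstant)
})
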