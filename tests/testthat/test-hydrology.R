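# Daily water dynamics: single-process contracts, the full daily step, and
# equivalence of the R reference path with the compiled period core.

test_that("infiltration respects water, capacity and cover feedback", {
  soil <- soilParams()
  expect_equal(infiltrate(0, 0.5, soil, 0.10), 0)
  expect_equal(infiltrate(10, 0.5, soil, soil@porosity), 0)
  # more cover never reduces infiltration (root-porosity feedback)
  low <- infiltrate(5, 0, soil, 0.10)
  high <- infiltrate(5, 1, soil, 0.10)
  expect_gte(high, low)
  expect_error(infiltrate(5, 1.5, soil, 0.1), "cover")
})

test_that("runoff routing conserves water and is damped by cover", {
  dem <- slopedDem(4, 4)
  s <- matrix(2, 4, 4)
  bare <- routeRunoff(s, dem, matrix(0, 4, 4))
  expect_equal(sum(bare$surface), sum(s))      # closed boundary
  expect_true(all(bare$runoffOut[-16] > 0))  # all but the pit cell drain

  flat <- routeRunoff(s, flatDem(4, 4), matrix(0, 4, 4))
  expect_equal(flat$surface, s)                # no gradient, no movement

  veg <- routeRunoff(s, dem, matrix(0.9, 4, 4))
  expect_true(all(veg$runoffOut <= bare$runoffOut))
  expect_lt(max(veg$runoffOut), max(bare$runoffOut))
  expect_error(routeRunoff(s[1:2, ], dem, matrix(0, 4, 4)), "shape")
})

test_that("evaporation vanishes at residual moisture and under full shade", {
  soil <- soilParams()
  expect_equal(evaporate(soil@residualWater, 0, 30, soil), 0)
  expect_equal(evaporate(0.10, 1, 30, soil, shading = 1), 0)
  withCover <- evaporate(0.10, 0.5, 30, soil)
  noCover <- evaporate(0.10, 0, 30, soil)
  expect_lt(withCover, noCover)
})

test_that("transpiration follows roots, wilting points and uptake rates", {
  soil <- soilParams()
  st <- tinyStrategies()
  dry <- transpire(0.05, 0.05, setNames(rep(0.2, 4), st$id), st, 30, soil)
  expect_true(all(dry == 0))

  # annuals have no access to the lower layer
  wetBelow <- transpire(0.05, 0.12, setNames(rep(0.2, 4), st$id), st, 30,
                        soil)
  expect_equal(wetBelow["ann.base", "lower"], 0)
  expect_equal(sum(wetBelow["ann.base", ]), 0)
  expect_gt(wetBelow["shr.base", "lower"], 0)

  # doubling the uptake rate doubles unstressed transpiration
  two <- tinyStrategies(uptake2 = 0.45)
  two["per.base", "uptakeRate"] <- 0.9
  tr <- transpire(0.124, 0.124, setNames(c(0.1, 0, 0, 0.1), two$id), two,
                  25, soil)
  expect_equal(sum(tr["per.base", ]) / sum(tr["per.twin", ]), 2,
               tolerance = 1e-12)
})

test_that("a dry day on a dry bare landscape changes nothing", {
  soil <- soilParams()
  st <- tinyStrategies()
  nr <- 3; nc <- 3
  state <- list(surface = matrix(0, nr, nc),
                thetaUpper = matrix(soil@residualWater, nr, nc),
                thetaLower = matrix(soil@residualWater, nr, nc))
  cover <- matrix(0, nr * nc, 4, dimnames = list(NULL, st$id))
  out <- stepDay(state, 0, 28, 20, cover, st, soil, flatDem(nr, nc))
  expect_equal(out$state, state)
  expect_true(all(out$fluxes$evaporation == 0))
  expect_true(all(out$fluxes$transpiration == 0))
})

test_that("rain on a dry flat cell infiltrates fully", {
  soil <- soilParams()
  st <- tinyStrategies()
  state <- list(surface = matrix(0, 1, 1),
                thetaUpper = matrix(0.06, 1, 1),
                thetaLower = matrix(0.06, 1, 1))
  cover <- matrix(0, 1, 4, dimnames = list(NULL, st$id))
  out <- stepDay(state, 10, 28, 20, cover, st, soil, flatDem(1, 1))
  expect_equal(out$fluxes$infiltration, 10)
  expect_equal(out$fluxes$runoffOut, 0)
  expect_equal(out$state$surface[1, 1], 0)
})

test_that("soil moisture stays within physical bounds under random forcing", {
  set.seed(31)
  soil <- soilParams()
  st <- tinyStrategies()
  state <- randomHydroState(3, 3, soil)
  cover <- matrix(runif(9 * 4, 0, 0.2), 9, 4, dimnames = list(NULL, st$id))
  dem <- slopedDem(3, 3)
  for (d in 1:150) {
    p <- if (runif(1) < 0.3) rgamma(1, 0.7, scale = 10) else 0
    out <- stepDay(state, p, runif(1, 15, 38), sample(365, 1), cover, st,
                   soil, dem)
    state <- out$state
    expect_true(all(state$thetaUpper >= soil@residualWater - 1e-12))
    expect_true(all(state$thetaUpper <= soil@porosity + 1e-12))
    expect_true(all(state$thetaLower >= soil@residualWater - 1e-12))
    expect_true(all(state$thetaLower <= soil@porosity + 1e-12))
    expect_true(all(state$surface >= 0))
  }
})

test_that("cover monotonicity: more cover, less evaporation, no less infiltration", {
  soil <- soilParams()
  st <- tinyStrategies()
  dem <- flatDem(2, 2)
  base <- list(surface = matrix(0, 2, 2), thetaUpper = matrix(0.11, 2, 2),
               thetaLower = matrix(0.10, 2, 2))
  mkCover <- function(tot) matrix(tot / 4, 4, 4,
                                  dimnames = list(NULL, st$id))
  lo <- stepDay(base, 6, 30, 40, mkCover(0.2), st, soil, dem)
  hi <- stepDay(base, 6, 30, 40, mkCover(0.8), st, soil, dem)
  expect_true(all(hi$fluxes$evaporation <= lo$fluxes$evaporation))
  expect_true(all(hi$fluxes$infiltration >= lo$fluxes$infiltration))
})

test_that("the compiled period core reproduces the R reference step", {
  set.seed(99)
  soil <- soilParams()
  st <- assembleStrategyTypes("browsing")
  nr <- 4; nc <- 3; ncell <- nr * nc
  cover <- matrix(runif(ncell * nrow(st), 0, 0.04), ncell, nrow(st),
                  dimnames = list(NULL, st$id))
  dem <- slopedDem(nr, nc)
  state <- list(surface = matrix(0.4, nr, nc),
                thetaUpper = matrix(0.10, nr, nc),
                thetaLower = matrix(0.07, nr, nc))
  prec <- c(12, 0, 3, 0, 8, 25, 0, 0, 1, 0)
  tmp <- runif(10, 18, 35)
  doys <- 295:304
  stR <- state
  Tsum <- matrix(0, ncell, nrow(st))
  Esum <- numeric(ncell)
  for (d in 1:10) {
    out <- stepDay(stR, prec[d], tmp[d], doys[d], cover, st, soil, dem)
    stR <- out$state
    Tsum <- Tsum + out$fluxes$transpByType
    Esum <- Esum + out$fluxes$evaporation
  }
  h <- savannaSim:::.hydroPeriod(
    as.numeric(state$thetaUpper), as.numeric(state$thetaLower),
    as.numeric(state$surface), cover, st, savannaSim:::.typeGroups(st),
    prec, tmp, doys, rep(TRUE, 10), savannaSim:::.receiverIndex(dem),
    savannaSim:::.soilVector(soil), savannaSim:::.hydroConstants(),
    perType = TRUE)
  expect_lt(max(abs(h$thetaU - as.numeric(stR$thetaUpper))), 1e-9)
  expect_lt(max(abs(h$thetaL - as.numeric(stR$thetaLower))), 1e-9)
  expect_lt(max(abs(h$surface - as.numeric(stR$surface))), 1e-9)
  expect_lt(max(abs(h$transpType - Tsum)), 1e-9)
  expect_lt(max(abs(h$evapSum - Esum)), 1e-9)
})
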