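# Biweekly vegetation dynamics: growth, mortality, dispersal,
# establishment, and the shared cover budget.

test_that("growth needs water and space and follows the stated rule", {
  st <- data.frame(tVeg = 0.5, maxGrow = 1)
  expect_equal(grow(0.2, 0, st, 1), 0)
  expect_equal(grow(0.2, 10, st, 0), 0)
  expect_equal(grow(0.2, 10, st, 1, wue = 0.01), 0.05)
  # caps: biweekly maximum and free space
  expect_equal(grow(0.2, 1000, data.frame(tVeg = 0.5, maxGrow = 0.04), 1,
                    wue = 0.01), 0.04)
  expect_equal(grow(0.2, 1000, st, 0.03, wue = 0.01), 0.03)
})

test_that("end-of-season mortality follows the senescence/stress split", {
  per <- data.frame(mrd = 0, meta = "perennial")
  expect_equal(endSeasonMortality(0.4, 0, per), 0.4)
  per$mrd <- 0.54
  expect_equal(endSeasonMortality(0.4, 1, per), 0.4 * (1 - 0.54))
  expect_equal(endSeasonMortality(0.4, 0, per, b0 = 0.25),
               0.4 * (1 - 0.54 * 0.25))
  ann <- data.frame(mrd = 1, meta = "annual")
  expect_equal(endSeasonMortality(0.7, 0.3, ann), 0)
  expect_error(endSeasonMortality(0.4, 1.4, per), "stressFrac")
})

test_that("dispersal fixed points and absence are respected", {
  st <- tinyStrategies()
  nr <- 6; nc <- 6
  cover <- matrix(0, nr * nc, 4, dimnames = list(NULL, st$id))
  cover[, "per.base"] <- 0.37
  set.seed(1)
  sb <- disperse(cover, st, Inf, nr, nc)
  # uniform grass cover is a fixed point of the neighbourhood mean
  expect_equal(unique(round(sb[, "per.base"], 12)), 0.37)
  # absent types receive no seed
  expect_true(all(sb[, c("shr.base", "ann.base", "per.twin")] == 0))
  expect_error(disperse(cover, st, -3, nr, nc), "positive")
})

test_that("herbivore-mediated shrub dispersal scales with animal density", {
  st <- tinyStrategies()
  nr <- 10; nc <- 10
  cover <- matrix(0, nr * nc, 4, dimnames = list(NULL, st$id))
  cover[, "shr.base"] <- 0.3
  vc <- vegConstants()
  countEvents <- function(sr, seed) {
    set.seed(seed)
    sb <- disperse(cover, st, sr, nr, nc, vc)
    # the kernel part is uniform (0.3 * factor); extra mass comes from
    # long-distance events of ldSeed each
    base <- vc$shrubSeedFactor * 0.3
    sum(sb[, "shr.base"] - base) / vc$ldSeed
  }
  e10 <- mean(vapply(1:60, function(s) countEvents(10, s), 0))
  e50 <- mean(vapply(1:60, function(s) countEvents(50, s), 0))
  expect_gt(e10, 0)
  expect_equal(e10 / e50, 5, tolerance = 0.25)
})

test_that("establishment is gated by moisture and space with unbiased rounding", {
  st <- tinyStrategies()
  sb <- matrix(1, 50, 4, dimnames = list(NULL, st$id))
  vc <- vegConstants(pEst = 0.05)
  dry <- establish(sb, rep(0.05, 50), rep(1, 50), st, vc)
  expect_true(all(dry == 0))
  noSpace <- establish(sb, rep(0.12, 50), rep(0, 50), st, vc)
  expect_true(all(noSpace == 0))
  set.seed(12)
  inc <- replicate(200, mean(establish(sb, rep(0.2, 50), rep(1, 50), st,
                                       vc)[, "per.base"]))
  expect_equal(mean(inc), 0.05, tolerance = 0.005)
})

test_that("the empty landscape is absorbing and cover stays in budget", {
  st <- tinyStrategies()
  nr <- 4; nc <- 4
  veg <- list(cover = matrix(0, 16, 4, dimnames = list(NULL, st$id)),
              seedBank = matrix(0, 16, 4, dimnames = list(NULL, st$id)))
  transp <- matrix(5, 16, 4)
  set.seed(2)
  out <- stepBiweek(veg, transp, rep(0.12, 16), st, 40, nr, nc)
  expect_true(all(out$cover == 0))
  expect_true(all(out$seedBank == 0))

  # near-saturated landscape: total cover never exceeds 1
  veg2 <- list(cover = matrix(0.24, 16, 4, dimnames = list(NULL, st$id)),
               seedBank = matrix(1, 16, 4, dimnames = list(NULL, st$id)))
  for (k in 1:10) {
    veg2 <- stepBiweek(veg2, transp, rep(0.2, 16), st, 40, nr, nc)
    expect_true(all(rowSums(veg2$cover) <= 1 + 1e-9))
    expect_true(all(veg2$cover >= 0))
  }
})

test_that("a single unstressed type gains cover", {
  st <- tinyStrategies()
  veg <- list(cover = matrix(0, 16, 4, dimnames = list(NULL, st$id)),
              seedBank = matrix(0, 16, 4, dimnames = list(NULL, st$id)))
  veg$cover[, "per.base"] <- 0.3
  transp <- matrix(0, 16, 4); transp[, 1] <- 8
  colnames(transp) <- st$id
  transp <- transp[, st$id]
  transp[] <- 0; transp[, "per.base"] <- 8
  set.seed(3)
  out <- stepBiweek(veg, transp, rep(0.2, 16), st, 40, 4, 4)
  expect_true(all(out$cover[, "per.base"] > 0.3))
})

test_that("a water-uptake advantage wins cover over repeated biweeks", {
  # two perennials identical except the uptake rate, sharing limited water
  st <- tinyStrategies(uptake2 = 0.45)
  soil <- soilParams()
  groups <- savannaSim:::.typeGroups(st)
  nr <- 5; nc <- 5; ncell <- 25
  cover <- matrix(0, ncell, 4, dimnames = list(NULL, st$id))
  cover[, c("per.base", "per.twin")] <- 0.15
  veg <- list(cover = cover, seedBank = cover)
  thU <- rep(soil@fcUpper, ncell); thL <- rep(soil@fcLower, ncell)
  sf <- rep(0, ncell)
  clim <- tinyClimate(1, seed = 77)
  doy <- savannaSim:::.calendarDoy(1:365)
  set.seed(9)
  for (b in 1:10) {
    seg <- (93 + (b - 1) * 14):(92 + b * 14)   # within the wet season
    h <- savannaSim:::.hydroPeriod(
      thU, thL, sf, veg$cover, st, groups, clim@precip[seg],
      clim@temp[seg], doy[seg], rep(TRUE, 14), rep(-1L, ncell),
      savannaSim:::.soilVector(soil), savannaSim:::.hydroConstants(),
      perType = TRUE)
    thU <- h$thetaU; thL <- h$thetaL; sf <- h$surface
    veg <- stepBiweek(veg, h$transpType, h$thetaUCellSum / 14, st, 40,
                      nr, nc)
  }
  gainBase <- mean(veg$cover[, "per.base"]) - 0.15
  gainTwin <- mean(veg$cover[, "per.twin"]) - 0.15
  expect_gt(gainBase, gainTwin)
})
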