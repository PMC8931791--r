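# End-of-season selective biomass removal: conversions, demand, the
# cell-by-cell removal loop against a brute-force oracle, and deficit
# bookkeeping.

test_that("the rainfall correction factor is a clipped ratio", {
  expect_equal(rainCorrection(291.3, 291.3), 1.0)
  expect_equal(rainCorrection(0, 291.3), 0.2)
  expect_equal(rainCorrection(3 * 291.3, 291.3), 2.0)
  expect_error(rainCorrection(100, 0), "positive")
})

test_that("cover-biomass conversion round-trips exactly", {
  expect_equal(coverToBiomass(0, 8, 1.3), 0)
  expect_equal(coverToBiomass(0.4, 8, 1), 3.2)
  set.seed(4)
  x <- runif(50)
  expect_equal(biomassToCover(coverToBiomass(x, 8, 0.7), 8, 0.7), x,
               tolerance = 1e-14)
  expect_error(biomassToCover(1, 8, 0), "positive")
})

test_that("herd demand follows the livestock-unit arithmetic", {
  expect_equal(neededBiomass(40, 2.25), 184.78125)
  expect_equal(neededBiomass(10, 0), 0)
  expect_equal(neededBiomass(10, 2.25) / neededBiomass(50, 2.25), 5)
  expect_error(neededBiomass(0, 2.25), "positive")
})

test_that("the defended fraction bounds what herbivores can take", {
  expect_equal(edibleBiomass(100, 1), 0)
  expect_equal(edibleBiomass(100, 0), 100)
  expect_equal(edibleBiomass(100, 0.95), 5)
  expect_error(edibleBiomass(100, 1.2), "defense")
})

# brute-force allocation: remove the demand in many small parcels, each
# split by the pref x edible weights, excluding exhausted types; the limit
# of small parcels is the declared one-shot proportional rule with caps
bruteAllocate <- function(demand, edible, prefs, step = 1e-3) {
  take <- numeric(length(edible))
  remaining <- demand
  while (remaining > 1e-9) {
    open <- (edible - take) > 1e-12
    w <- prefs * edible * open
    if (sum(w) <= 0) break
    d <- min(step, remaining)
    share <- pmin(d * w / sum(w), edible - take)
    take <- take + share
    remaining <- remaining - sum(share)
    if (sum(share) < 1e-15) break
  }
  take
}

test_that("within-cell allocation matches a brute-force oracle", {
  set.seed(8)
  for (k in 1:5) {
    edible <- runif(4, 0, 2)
    prefs <- runif(4, 0, 1.5)
    demand <- runif(1, 0, sum(edible))
    fast <- savannaSim:::.allocateWithinCell(demand, edible, prefs)
    slow <- bruteAllocate(demand, edible, prefs)
    expect_equal(sum(fast), min(demand, sum(fast)), tolerance = 1e-9)
    expect_true(all(fast <= edible + 1e-12))
    expect_equal(fast, slow, tolerance = 0.02)
  }
})

test_that("removal handles exhaustion, pure preference and symmetry", {
  # demand above the edible total removes everything
  edible <- matrix(runif(12, 0, 3), 4, 3)
  set.seed(5)
  res <- removeBiomass(edible, 100, c(1, 1, 1))
  expect_equal(res$removed, edible)
  expect_equal(res$deficit, 100 - sum(edible))

  # single cell, two types, one preferred exclusively
  one <- matrix(c(2, 2), 1, 2)
  res2 <- removeBiomass(one, 1, c(1, 0))
  expect_equal(as.numeric(res2$removed), c(1, 0))

  # equal preference and equal pools split evenly
  res3 <- removeBiomass(one, 2, c(1, 1))
  expect_equal(as.numeric(res3$removed), c(1, 1))
  expect_error(removeBiomass(one, -1, c(1, 1)), "negative")
})

test_that("expected removal is uniform across identical cells", {
  edible <- matrix(1, 10, 1)   # ten identical cells, demand strips half
  tot <- numeric(10)
  for (s in 1:400) {
    set.seed(s)
    tot <- tot + rowSums(removeBiomass(edible, 5, 1)$removed)
  }
  expect_lt(max(abs(tot / 400 - 0.5)), 0.1)
})

test_that("denser herds never remove less", {
  st <- assembleStrategyTypes("grazing")
  cover <- matrix(runif(9 * nrow(st), 0, 0.04), 9, nrow(st),
                  dimnames = list(NULL, st$id))
  rem <- vapply(c(50, 30, 10), function(sr) {
    set.seed(77)
    applyHerbivory(cover, st, sr, 2.25, 1)$outcome$removedTotal
  }, 0)
  expect_true(all(diff(rem) >= -1e-9))
})

test_that("the full herbivory pipeline conserves biomass and respects defense", {
  st <- assembleStrategyTypes("browsing")
  set.seed(6)
  cover <- matrix(runif(25 * nrow(st), 0, 0.04), 25, nrow(st),
                  dimnames = list(NULL, st$id))
  cf <- 1.4
  out <- applyHerbivory(cover, st, 20, 2.25 * 25 / 900, cf)
  conv <- rep(st$convBm, each = 25)
  # biomass balance: cover loss x conversion x cf equals removed biomass
  expect_equal((cover - out$cover) * conv * cf, out$outcome$removed,
               tolerance = 1e-9)
  # removal never exceeds the edible (undefended) share
  defended <- cover * conv * cf * rep(st$defense, each = 25)
  expect_true(all(out$cover * conv * cf >= defended - 1e-9))
  expect_true(all(out$cover <= cover + 1e-12))

  # nothing edible: state unchanged, deficit equals demand
  stArm <- st; stArm$defense <- 1
  out2 <- applyHerbivory(cover, stArm, 20, 2.25, 1)
  expect_equal(out2$cover, cover)
  expect_equal(out2$outcome$deficit, out2$outcome$demand)
  expect_equal(out2$outcome$effectiveSr, Inf)

  # effectively no herbivores: demand ~ 0
  out3 <- applyHerbivory(cover, st, 1e12, 2.25, 1)
  expect_equal(out3$cover, cover, tolerance = 1e-9)
})

test_that("effective stocking rate scales with the met demand", {
  expect_equal(effectiveStocking(40, 100, 100), 40)
  expect_equal(effectiveStocking(40, 100, 50), 80)
  expect_equal(effectiveStocking(40, 100, 0), Inf)
  expect_error(effectiveStocking(40, 100, 120), "demand")
})
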