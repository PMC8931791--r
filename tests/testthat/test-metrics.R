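# Community and water-use analytics against closed forms and brute-force
# oracles.

test_that("richness applies the strict 2.5% threshold", {
  expect_equal(richness(c(A = 10, B = 2, C = 3)), 2L)
  expect_equal(richness(c(A = 0, B = 0)), 0L)
  expect_equal(richness(c(A = 2.5)), 0L)         # strictly greater
  expect_equal(richness(c(A = 2.5000001)), 1L)
  expect_error(richness(c(A = -1)), "non-negative")
})

test_that("Shannon and Pielou indices match hand evaluations", {
  even <- shannonPielou(c(a = 10, b = 10, c = 10, d = 10))
  expect_equal(even$J, 1)
  expect_equal(even$H, log(4))

  single <- shannonPielou(c(a = 50, b = 1))
  expect_equal(single$S, 1L)
  expect_equal(single$H, 0)
  expect_equal(single$J, 0)

  mix <- shannonPielou(c(a = 50, b = 25, c = 25))
  expect_equal(mix$H, 1.039721, tolerance = 1e-6)
  expect_equal(mix$J, 0.946395, tolerance = 1e-6)
  expect_error(shannonPielou(c(a = 0, b = 0)), "zero")
})

test_that("evenness is invariant to abundance rescaling and maximal when uniform", {
  set.seed(15)
  for (k in 1:10) {
    x <- setNames(runif(6, 3, 50), letters[1:6])
    expect_equal(shannonPielou(x)$J, shannonPielou(10 * x)$J,
                 tolerance = 1e-12)
    expect_lte(shannonPielou(x)$J, 1 + 1e-12)
  }
})

test_that("epsilon squared matches its rank-statistic definition", {
  expect_equal(epsilonSquared(0, 30)$e2, 0)
  expect_equal(epsilonSquared(0, 30)$label, "small")
  expect_equal(epsilonSquared(0.15 * 29, 30)$label, "medium")
  expect_equal(epsilonSquared(0.27 * 29, 30)$label, "large")
  # two-group toy data: H from the standard rank test, e2 = H / (n - 1)
  x <- c(1.1, 2.3, 3.1, 4.8); y <- c(2.0, 5.5, 6.1, 7.2)
  H <- unname(kruskal.test(list(x, y))$statistic)
  e2 <- epsilonSquared(H, 8)$e2
  expect_equal(e2, H / ((8^2 - 1) / (8 + 1)), tolerance = 1e-12)
})

test_that("Cohen's d equals the pooled-sd formula", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(16)
  x <- rnorm(12, 1); y <- rnorm(9)
  sp <- sqrt((11 * var(x) + 8 * var(y)) / 19)
  expect_equal(cohensD(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohensD(1, c(1, 2)), "2 values")
  expect_error(cohensD(c(1, 1), c(1, 1)), "pooled")
})

test_that("functional dispersion matches geometry and a brute-force oracle", {
  pt <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(functionalDispersion(pt, c(1, 0))$fdis, 0)
  expect_equal(functionalDispersion(pt, c(1, 1))$fdis, 2.5)  # d/2 = 5/2

  set.seed(17)
  xy <- matrix(rnorm(10), 5, 2)
  w <- runif(5)
  got <- functionalDispersion(xy, w)
  cen <- c(sum(w * xy[, 1]), sum(w * xy[, 2])) / sum(w)
  dist <- apply(xy, 1, function(p) sqrt(sum((p - cen)^2)))
  expect_equal(got$fdis, sum(w * dist) / sum(w), tolerance = 1e-12)
  expect_error(functionalDispersion(xy, rep(0, 5)), "positive")
})

test_that("functional dispersion is invariant under rigid motions", {
  set.seed(18)
  xy <- matrix(rnorm(12), 6, 2)
  w <- runif(6)
  phi <- 0.7
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  moved <- xy %*% rot + matrix(c(5, -2), 6, 2, byrow = TRUE)
  expect_equal(functionalDispersion(xy, w)$fdis,
               functionalDispersion(moved, w)$fdis, tolerance = 1e-12)
})

test_that("factor extraction separates anti-correlated blocks", {
  set.seed(19)
  n <- 60
  drv <- rnorm(n)
  block1 <- sapply(1:3, function(i) drv + rnorm(n, 0, 0.05))
  block2 <- sapply(1:3, function(i) -drv + rnorm(n, 0, 0.05))
  m <- cbind(block1, block2)
  colnames(m) <- c("s1", "s2", "s3", "p1", "p2", "p3")
  fs <- factorStructure(m, orientPositive = c("s1", "s2", "s3"))
  expect_gte(fs$retained, 1L)
  expect_true(all(fs$loadings[1:3, 1] > 0.9))
  expect_true(all(fs$loadings[4:6, 1] < -0.9))

  # a second independent direction with eigenvalue > 1 is retained, capped
  # at two factors
  extra <- rnorm(n)
  m2 <- cbind(block1, block2,
              e1 = extra + rnorm(n, 0, 0.05),
              e2 = extra + rnorm(n, 0, 0.05),
              e3 = extra + rnorm(n, 0, 0.05))
  fs2 <- factorStructure(m2)
  expect_equal(fs2$retained, 2L)
  expect_equal(sum(eigen(cor(m2))$values > 1), 2)

  expect_warning(factorStructure(cbind(m, const = 1)), "constant")
  expect_error(factorStructure(matrix(1, 10, 3)), "constant")
})

test_that("k-means clustering and WCSS match brute force", {
  pts <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
               matrix(rnorm(10, 4, 0.05), 5, 2))
  rownames(pts) <- paste0("t", 1:10)
  cl <- clusterWcss(pts, 2)
  expect_equal(length(unique(cl$assignments[1:5])), 1L)
  expect_equal(length(unique(cl$assignments[6:10])), 1L)
  expect_false(cl$assignments[1] == cl$assignments[6])

  # WCSS recomputed from assignments
  for (k in unique(cl$assignments)) {
    own <- pts[cl$assignments == k, , drop = FALSE]
    cen <- colMeans(own)
    expect_equal(cl$wcss[k], sum(sweep(own, 2, cen)^2), tolerance = 1e-9)
  }

  same <- matrix(1, 4, 2)
  expect_equal(sum(clusterWcss(same, 2)$wcss), 0)
  expect_error(clusterWcss(pts, 11), "exceeds")

  # total WCSS non-increasing in k
  tot <- vapply(1:3, function(k) sum(clusterWcss(pts, k)$wcss), 0)
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("water use and wet-season moisture follow their definitions", {
  expect_equal(waterUse(0, 10), 0)
  expect_equal(waterUse(5, 5), 100)
  expect_equal(waterUse(44.2, 50), 88.4)
  expect_equal(waterUse(0, 0), 0)
  expect_error(waterUse(5, 4), "ET")

  expect_equal(wetSeasonMoisture(rep(11.4, 365), c(100, 200)), 11.4)
  expect_true(is.na(wetSeasonMoisture(rep(11.4, 365), NULL)))
  y <- seq(1, 365)
  expect_equal(wetSeasonMoisture(y, c(11, 20)), mean(11:20))
})
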