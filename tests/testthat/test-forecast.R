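test_that("mean karyotype is the frequency-weighted copy-number centroid", {
  d <- setNames(1, kstr(diploid()))
  expect_equal(meanKaryotype(d), rep(2, 22))
  mix <- setNames(c(0.5, 0.5), c(kstr(diploid()), kstr(rep(4L, 22))))
  expect_equal(meanKaryotype(mix), rep(3, 22))
  asym <- setNames(c(0.25, 0.75), c(kstr(kAlt(1, 1)), kstr(kAlt(1, 3))))
  expect_equal(meanKaryotype(asym)[1], 0.25 * 1 + 0.75 * 3)
})

test_that("the angle metric reports degrees in [0, 180]", {
  v <- rnorm(22)
  expect_equal(angleMetric(v, v), 0, tolerance = 1e-5)
  expect_equal(angleMetric(v, -v), 180, tolerance = 1e-5)
  e1 <- c(1, rep(0, 21)); e2 <- c(0, 1, rep(0, 20))
  expect_equal(angleMetric(e1, e2), 90)
  expect_warning(out <- angleMetric(rep(0, 22), v), "zero change")
  expect_true(is.nan(out))
})

test_that("the Monte Carlo angle null is calibrated", {
  # median angle between random unit vectors in 22-D is 90 degrees
  set.seed(1)
  ang <- karyofit:::randomNullAngles(2e5)
  expect_lt(abs(median(ang) - 90), 0.25)
  # perfectly aligned data gives a minimal one-sided p
  res <- angleNullTest(list(c(0, 0, 0), c(0, 0)), nIter = 500, seed = 2)
  expect_lte(res$p_value, 2 / 500)
  expect_equal(res$T_obs, 0)
  # p-values are roughly uniform under the null itself
  set.seed(3)
  ps <- vapply(1:60, function(r) {
    obs <- split(karyofit:::randomNullAngles(12), rep(1:3, each = 4))
    angleNullTest(obs, nIter = 300, seed = 1000 + r)$p_value
  }, numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(angleNullTest(list()), "at least one")
})

test_that("Wasserstein distance is an exact optimal-transport cost", {
  d <- setNames(1, kstr(diploid()))
  expect_equal(wassersteinDist(d, d), 0)
  d2 <- setNames(1, kstr(kAlt(1, 4)))
  expect_equal(wassersteinDist(d, d2), 2)          # single transport arc
  expect_equal(wassersteinDist(d, d2, ground = "manhattan"), 2)
  mix <- setNames(c(0.5, 0.5), c(kstr(diploid()), kstr(kAlt(1, 3))))
  expect_equal(wassersteinDist(mix, d2),
               0.5 * 2 + 0.5 * 1)
  # symmetric
  expect_equal(wassersteinDist(mix, d2), wassersteinDist(d2, mix))
})

test_that("the transportation simplex matches a quadratic-program oracle", {
  skip_if_not_installed("quadprog")
  # LP solved as the ridge-regularized QP limit over the transport polytope
  oracle <- function(a, b, C) {
    m <- length(a); n <- length(b); nv <- m * n
    A <- matrix(0, m + n, nv)
    for (i in 1:m) A[i, ((1:n) - 1) * m + i] <- 1
    for (j in 1:n) A[m + j, (j - 1) * m + (1:m)] <- 1
    A <- A[-(m + n), , drop = FALSE]
    sol <- quadprog::solve.QP(diag(1e-8, nv), -as.numeric(C),
                              t(rbind(A, diag(nv))),
                              c(a, b[-n], rep(0, nv)), meq = m + n - 1)
    sum(as.numeric(C) * sol$solution)
  }
  set.seed(12)
  for (r in 1:10) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    C <- matrix(runif(m * n, 0, 5), m, n)
    expect_equal(karyofit:::transportPlan(a, b, C)$cost, oracle(a, b, C),
                 tolerance = 1e-5)
  }
})

test_that("Wasserstein satisfies the triangle inequality on random toys", {
  set.seed(13)
  randDist <- function() {
    km <- matrix(sample(1:5, 5 * 22, TRUE), 5)
    w <- runif(5)
    setNames(w / sum(w), formatKaryotype(km))
  }
  for (r in 1:10) {
    d1 <- randDist(); d2 <- randDist(); d3 <- randDist()
    expect_lte(wassersteinDist(d1, d3),
               wassersteinDist(d1, d2) + wassersteinDist(d2, d3) + 1e-9)
  }
})

test_that("overlap coefficient and baseline behave as set statistics", {
  d1 <- setNames(c(0.6, 0.4), c(kstr(diploid()), kstr(kAlt(1, 3))))
  d2 <- setNames(c(0.4, 0.6), c(kstr(diploid()), kstr(kAlt(1, 3))))
  expect_equal(overlapCoefficient(d1, d1), 1)
  expect_equal(overlapCoefficient(d1, d2), 0.8)
  d3 <- setNames(1, kstr(kAlt(9, 5)))
  expect_equal(overlapCoefficient(d1, d3), 0)
  expect_identical(noEvolutionBaseline(d1), d1)
  expect_equal(wassersteinDist(noEvolutionBaseline(d1), d1), 0)
  expect_warning(angleMetric(meanKaryotype(noEvolutionBaseline(d1)) -
                               meanKaryotype(d1), rnorm(22)))
})

test_that("beat-baseline fractions count strict improvements only", {
  expect_equal(beatBaselineFraction(c(1, 1), c(2, 2)), 1)
  expect_equal(beatBaselineFraction(c(3, 3), c(2, 2)), 0)
  expect_equal(beatBaselineFraction(rep(1, 20), c(rep(0.5, 13), rep(2, 7))),
               0.35)
  expect_equal(beatBaselineFraction(1, 1), 0)   # ties do not beat
  expect_error(beatBaselineFraction(numeric(0), numeric(0)), "records")
})

test_that("forecasts reduce to the start at horizon zero and are seeded", {
  k2 <- kstr(diploid()); k3 <- kstr(kAlt(1, 3))
  lut <- LUTLandscape(setNames(c(0.5, 0.6), c(k2, k3)))
  start <- setNames(c(0.5, 0.5), c(k2, k3))
  expect_equal(forecastPopulation(lut, start, 0, p = 0), start)
  f1 <- forecastPopulation(lut, start, 5, nReplicates = 2, seed = 4, p = 0)
  f2 <- forecastPopulation(lut, start, 5, nReplicates = 2, seed = 4, p = 0)
  expect_identical(f1, f2)
})

test_that("two-clone forecasts match the logistic replicator solution", {
  k2 <- kstr(diploid()); k3 <- kstr(kAlt(1, 3))
  lut <- LUTLandscape(setNames(c(0.5, 0.6), c(k2, k3)))
  start <- setNames(c(0.5, 0.5), c(k2, k3))
  fc <- forecastPopulation(lut, start, 10, nReplicates = 30, seed = 6,
                           p = 0, nCells = 2000)
  pred <- exp(1) / (1 + exp(1))
  expect_lt(abs(fc[k3] - pred), 0.02)
})

test_that("forecast distributions stabilize as replicates accumulate", {
  k2 <- kstr(diploid()); k3 <- kstr(kAlt(1, 3))
  lut <- LUTLandscape(setNames(c(0.5, 0.6), c(k2, k3)))
  start <- setNames(c(0.5, 0.5), c(k2, k3))
  tv <- function(n, seedA, seedB) {
    fa <- forecastPopulation(lut, start, 8, nReplicates = n, seed = seedA,
                             p = 0, nCells = 500)
    fb <- forecastPopulation(lut, start, 8, nReplicates = n, seed = seedB,
                             p = 0, nCells = 500)
    ks <- union(names(fa), names(fb))
    ga <- setNames(numeric(length(ks)), ks); ga[names(fa)] <- fa
    gb <- setNames(numeric(length(ks)), ks); gb[names(fb)] <- fb
    sum(abs(ga - gb)) / 2
  }
  expect_lt(tv(16, 1, 2), tv(2, 3, 4) + 1e-9)
})
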