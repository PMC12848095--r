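test_that("frequent-clone identification applies the summed-count rule", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)), kstr(kAlt(2, 1)))
  cnt <- rbind(c(100L, 100L), c(5L, 3L), c(1L, 0L))
  rownames(cnt) <- S
  kc <- KaryoCounts(cnt, c(0, 10))
  expect_equal(identifyFrequentClones(kc, 5), S[1:2])
  expect_equal(identifyFrequentClones(kc, 1), S)
  expect_error(identifyFrequentClones(kc, 1000), "threshold")
  # |S| is non-increasing in the threshold
  sizes <- vapply(c(1, 2, 5, 100, 200),
                  function(m) length(identifyFrequentClones(kc, m)),
                  numeric(1L))
  expect_true(all(diff(sizes) <= 0))
})

test_that("replicator solution matches closed form and stays on simplex", {
  # neutrality
  x0 <- c(0.2, 0.3, 0.5)
  xt <- replicatorSolution(c(1, 1, 1), x0, c(0, 5, 50))
  expect_equal(xt, matrix(x0, 3, 3, byrow = TRUE), ignore_attr = TRUE)
  # two-clone closed form: x2(10) = 0.1 e^2 / (0.9 + 0.1 e^2)
  xt2 <- replicatorSolution(c(0, 0.2), c(0.9, 0.1), 10)
  expect_equal(xt2[1, 2], 0.1 * exp(2) / (0.9 + 0.1 * exp(2)),
               tolerance = 1e-12)
  expect_equal(xt2[1, 2], 0.4508531, tolerance = 1e-6)
  # simplex conservation
  set.seed(2)
  f <- rnorm(6, 0, 0.3)
  x0 <- runif(6); x0 <- x0 / sum(x0)
  xt3 <- replicatorSolution(f, x0, seq(0, 40, by = 5))
  expect_true(all(abs(rowSums(xt3) - 1) < 1e-9))
  expect_error(replicatorSolution(c(0, 1), c(0.6, 0.6), 1), "simplex")
})

test_that("replicator closed form agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  f <- c(0, 0.15, -0.1, 0.3)
  x0 <- c(0.4, 0.3, 0.2, 0.1)
  times <- seq(0, 25, by = 5)
  rhs <- function(t, x, parms)
    list(x * (f - sum(x * f)))
  num <- deSolve::ode(x0, times, rhs, NULL, rtol = 1e-10,
                      atol = 1e-12)[, -1]
  expect_equal(replicatorSolution(f, x0, times), num,
               ignore_attr = TRUE, tolerance = 1e-7)
})

test_that("neutral count data yields equal fitness estimates", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)), kstr(kAlt(2, 3)))
  cnt <- matrix(rep(c(500L, 300L, 200L), 4), nrow = 3)
  rownames(cnt) <- S
  kc <- KaryoCounts(cnt, c(0, 10, 20, 30))
  ff <- fitFrequentFitness(kc, S, inferenceConfig())
  expect_lt(diff(range(ff$fitness)), 1e-6)
})

test_that("noiseless replicator counts recover pairwise fitness differences", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)), kstr(kAlt(2, 3)))
  f <- c(0, 0.1, 0.2)
  kc <- replicatorCounts(S, f, c(0.8, 0.15, 0.05), seq(0, 60, 15))
  ff <- fitFrequentFitness(kc, S, inferenceConfig())
  est <- ff$fitness
  expect_lt(abs((est[2] - est[1]) - 0.1), 0.01)
  expect_lt(abs((est[3] - est[1]) - 0.2), 0.01)
  expect_true(ff$converged)
})

test_that("estimation error shrinks with per-passage sample size", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)), kstr(kAlt(2, 3)))
  f <- c(0, 0.1, 0.2)
  times <- seq(0, 60, 15)
  errAt <- function(n, reps) {
    vapply(seq_len(reps), function(r) {
      kc <- sampledReplicatorCounts(S, f, c(0.8, 0.15, 0.05), times, n)
      est <- fitFrequentFitness(kc, S, inferenceConfig())$fitness
      mean(abs(c(est[2] - est[1] - 0.1, est[3] - est[1] - 0.2)))
    }, numeric(1L))
  }
  set.seed(31)
  expect_gt(mean(errAt(500, 15)), mean(errAt(5000, 15)))
})

test_that("growth offset correction shifts without touching differences", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)))
  cnt <- rbind(c(300L, 100L), c(100L, 300L))
  rownames(cnt) <- S
  kc <- KaryoCounts(cnt, c(0, 10))
  f <- setNames(c(0.05, -0.05), S)
  g0 <- growthOffsetCorrection(f, kc, baseline = 0)
  w <- c(300, 100)
  expect_equal(sum(w * g0) / sum(w), 0, tolerance = 1e-12)
  g5 <- growthOffsetCorrection(f, kc, baseline = 0.5)
  expect_equal(unname(diff(g5)), unname(diff(f)))
  # equal clones at baseline 0.5 both land on 0.5
  feq <- setNames(c(0.1, 0.1), S)
  expect_equal(unname(growthOffsetCorrection(feq, kc, 0.5)), c(0.5, 0.5))
})

test_that("bootstrap CIs are seeded, consistent and cover the truth", {
  S <- c(kstr(diploid()), kstr(kAlt(1, 3)))
  f <- c(0, 0.15)
  times <- seq(0, 45, 15)
  set.seed(55)
  kcBig <- sampledReplicatorCounts(S, f, c(0.7, 0.3), times, 1e5)
  kcSmall <- sampledReplicatorCounts(S, f, c(0.7, 0.3), times, 100)
  b1 <- bootstrapFitness(kcBig, S, nBoot = 100, seed = 1)
  b2 <- bootstrapFitness(kcBig, S, nBoot = 100, seed = 1)
  expect_identical(b1$samples, b2$samples)
  widthOf <- function(b) mean(b$ci$upper - b$ci$lower)
  bs <- bootstrapFitness(kcSmall, S, nBoot = 100, seed = 1)
  expect_lt(widthOf(b1), widthOf(bs))
  # coverage of the pairwise difference at nominal 95%
  covered <- vapply(1:40, function(r) {
    kc <- sampledReplicatorCounts(S, f, c(0.7, 0.3), times, 400)
    b <- bootstrapFitness(kc, S, nBoot = 120, seed = r)
    d <- b$samples[, 2] - b$samples[, 1]
    ci <- quantile(d, c(0.025, 0.975))
    ci[1] <= 0.15 && 0.15 <= ci[2]
  }, logical(1L))
  expect_gte(mean(covered), 0.8)
})
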