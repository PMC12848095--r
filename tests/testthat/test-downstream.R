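flatLUTAround <- function(k, f = 0.5) {
  keys <- chartedRegion(kstr(k), 1)
  LUTLandscape(setNames(rep(f, length(keys)), keys))
}

test_that("delta-f profiles have 44 ordered one-step effects", {
  prof <- deltaFProfile(kstr(diploid()), flatLUTAround(diploid()))
  expect_length(prof$effects, 44L)
  expect_true(all(prof$effects == 0))
  expect_named(prof$effects[1:2], c("loss_chr1", "gain_chr1"))
  # linear landscape in chr5: effects only at the chr5 entries
  lin <- function(k) 0.01 * k[, 5]
  prof2 <- deltaFProfile(kstr(diploid()), lin)
  expect_equal(unname(prof2$effects["loss_chr5"]), -0.01)
  expect_equal(unname(prof2$effects["gain_chr5"]), 0.01)
  expect_true(all(prof2$effects[setdiff(names(prof2$effects),
                                        c("loss_chr5", "gain_chr5"))] == 0))
  # gains and losses cancel pairwise on any linear landscape
  lin2 <- function(k) 0.4 + k %*% seq(-0.01, 0.01, length.out = 22)
  prof3 <- deltaFProfile(kstr(diploid()), function(k) as.numeric(lin2(k)))
  expect_equal(sum(prof3$effects), 0, tolerance = 1e-12)
  # losses into zero-copy states are flagged nonviable
  prof4 <- deltaFProfile(kstr(kAlt(1, 1)), function(k) rep(0.5, nrow(k)))
  expect_true(is.na(prof4$effects["loss_chr1"]))
  expect_false(prof4$viable[1])
})

test_that("profile correlations use jointly viable entries", {
  lin <- function(k) as.numeric(0.4 + k %*% seq(-0.01, 0.01,
                                                length.out = 22))
  p1 <- deltaFProfile(kstr(diploid()), lin)
  expect_equal(profileCorrelation(p1, p1)$r, 1)
  p2 <- p1
  p2$effects <- -p1$effects
  expect_equal(profileCorrelation(p1, p2)$r, -1)
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
  flat <- deltaFProfile(kstr(diploid()), function(k) rep(1, nrow(k)))
  expect_warning(out <- profileCorrelation(p1, flat), "variance")
  expect_true(is.nan(out$r))
})

test_that("WGD classification uses the modal copy number with ties down", {
  expect_equal(wgdClassify(diploid()), "WGD-")
  expect_equal(wgdClassify(rep(4L, 22)), "WGD+")
  expect_equal(wgdClassify(rep(3L, 22)), "WGD+")
  tie <- c(rep(2L, 11), rep(3L, 11))
  expect_equal(wgdClassify(tie), "WGD-")
  expect_equal(unname(wgdClassify(rbind(diploid(), rep(4L, 22)))),
               c("WGD-", "WGD+"))
})

test_that("the permutation KS test is seeded and detects separation", {
  set.seed(20)
  vals <- c(rnorm(10, 0, 1), rnorm(10, 5, 1))
  labs <- rep(c("WGD-", "WGD+"), each = 10)
  r1 <- permutationKSTest(vals, labs, nPerm = 2000, seed = 3)
  r2 <- permutationKSTest(vals, labs, nPerm = 2000, seed = 3)
  expect_identical(r1, r2)
  expect_lte(r1$p_value, 0.01)
  # statistic agrees with the classical two-sample KS D
  expect_equal(r1$statistic,
               unname(suppressWarnings(ks.test(vals[1:10],
                                               vals[11:20])$statistic)))
  expect_error(permutationKSTest(vals, rep("a", 20)), "two levels")
  expect_error(permutationKSTest(vals[1:3], c("a", "a", "b")), "2 fits")
})

test_that("emergence features measure the mutational neighborhood", {
  theta <- setNames(c(0.5, 0.6, 0.55, 0.7),
                    c(kstr(diploid()), kstr(kAlt(1, 3)),
                      kstr(c(3L, 3L, diploid()[-(1:2)])), kstr(kAlt(9, 5))))
  zeta <- setNames(1, kstr(diploid()))
  psi <- kstr(kAlt(1, 3))
  ef <- emergenceFeatures(theta, zeta, psi)
  expect_setequal(ef$karyotype, setdiff(names(theta), names(zeta)))
  row1 <- ef[ef$karyotype == kstr(kAlt(1, 3)), ]
  expect_equal(row1$d1, 1)
  expect_equal(row1$d2 + row1$d3 + row1$d4 + row1$d5, 0)
  expect_true(row1$emerged)
  # candidate three steps out (kAlt(9,5)) sees zeta at d3
  row3 <- ef[ef$karyotype == kstr(kAlt(9, 5)), ]
  expect_equal(row3$d3, 1)
  # abundance weighting across two clones at distances 1 and 3
  zeta2 <- setNames(c(0.5, 0.5), c(kstr(kAlt(1, 2)), kstr(kAlt(1, 6))))
  theta2 <- c(theta, setNames(c(0.5, 0.5), names(zeta2)))
  ef2 <- emergenceFeatures(theta2, zeta2, character(0))
  cand <- ef2[ef2$karyotype == kstr(kAlt(1, 3)), ]
  expect_equal(cand$d1, 0.5)
  expect_equal(cand$d3, 0.5)
  # all-distant candidate has an empty neighborhood
  far <- setNames(0.1, kstr(rep(5L, 22)))
  ef3 <- emergenceFeatures(c(theta, far), zeta, character(0))
  expect_true(all(ef3[ef3$karyotype == names(far), paste0("d", 1:5)] == 0))
  expect_error(emergenceFeatures(theta, setNames(1, kstr(rep(7L, 22))),
                                 psi), "subset")
})

test_that("the emergence model recovers a d1-driven generative process", {
  set.seed(33)
  n <- 500
  feats <- data.frame(f = rnorm(n, 0.5, 0.1), d1 = runif(n),
                      d2 = runif(n), d3 = runif(n), d4 = runif(n),
                      d5 = runif(n))
  eta <- -3 + 5 * feats$d1
  feats$emerged <- runif(n) < plogis(eta)
  fit <- fitEmergenceModel(feats)
  expect_gt(fit$coefficients["d1"], 0)
  expect_lt(fit$p_values["d1"], 0.05)
  expect_false(fit$separation)
  # degenerate labels are rejected
  feats$emerged <- FALSE
  expect_error(fitEmergenceModel(feats), "both")
  # perfect separation is flagged
  feats$emerged <- feats$d1 > 0.15
  expect_warning(sepFit <- fitEmergenceModel(feats), "separation")
  expect_true(sepFit$separation)
})

test_that("non-overlapping trajectory sampling is node-disjoint", {
  chain <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"))
  tr <- sampleNonoverlappingTrajectories(chain, seed = 1)
  expect_length(tr, 1L)
  expect_equal(tr[[1]], c("a", "b", "c", "d"))
  two <- rbind(chain, data.frame(from = c("x", "y"), to = c("y", "z")))
  tr2 <- sampleNonoverlappingTrajectories(two, seed = 1)
  expect_length(tr2, 2L)
  # Y-shaped graph: stem passages never shared
  y <- data.frame(from = c("r", "s", "s"), to = c("s", "u", "v"))
  for (s in 1:10) {
    trs <- sampleNonoverlappingTrajectories(y, seed = s)
    all_nodes <- unlist(trs)
    expect_equal(anyDuplicated(all_nodes), 0L)
  }
  cyc <- data.frame(from = c("a", "b"), to = c("b", "a"))
  expect_error(sampleNonoverlappingTrajectories(cyc), "acyclic")
})

test_that("transition matrices combine kernel and growth correctly", {
  # 3-state chain on chr1 copies 1..3, everything else diploid
  ks <- vapply(1:3, function(c1) kstr(kAlt(1, c1)), character(1L))
  f <- setNames(c(0.1, 0.3, 0.2), ks)
  p <- 0.01; dt <- 1
  A <- buildTransitionMatrix(f, p, dt, maxDist = 2)
  expect_equal(dim(A), c(3L, 3L))
  # hand computation: per-daughter kernels restricted to the chain, other
  # chromosomes must stay diploid
  stay <- daughterKernel(2, p)[3]^21
  for (j in 1:3) {
    nj <- j  # chr1 copies of parent j
    kern <- daughterKernel(nj, p)
    raw <- vapply(1:3, function(i) {
      d <- i  # child copy number
      if (d <= 2 * nj) kern[d + 1] * stay else 0
    }, numeric(1L))
    expected <- raw / sum(raw) * exp(f[j] * dt)
    expect_equal(as.numeric(A[, j]), unname(expected), tolerance = 1e-12)
  }
  # p = 0: pure growth on the diagonal
  A0 <- buildTransitionMatrix(f, 0, dt)
  expect_equal(as.matrix(A0), diag(exp(f * dt)), ignore_attr = TRUE)
})

test_that("steady states match brute-force matrix powers", {
  ks <- vapply(1:3, function(c1) kstr(kAlt(1, c1)), character(1L))
  f <- setNames(c(0.1, 0.3, 0.2), ks)
  A <- buildTransitionMatrix(f, 0.02, 1)
  ss <- steadyState(A)
  expect_equal(sum(ss), 1, tolerance = 1e-9)
  M <- as.matrix(A)
  brute <- M
  for (i in 1:200) { brute <- brute %*% M; brute <- brute / max(brute) }
  ref <- brute[, 1] / sum(brute[, 1])
  expect_equal(unname(ss), unname(ref), tolerance = 1e-8)
  # p -> 0: all mass on the fittest state
  A0 <- buildTransitionMatrix(f, 1e-6, 1)
  ss0 <- steadyState(A0)
  expect_gte(unname(ss0[ks[2]]), 0.99)
  # identity-like operators are flagged
  expect_warning(steadyState(Matrix::Diagonal(3, 1)), "absorbing")
})

test_that("the dominance screen finds the error-threshold switch", {
  toy <- generateFixture("two_peak_toy", seed = 1)
  rates <- 10^seq(-5, -0.8, length.out = 6)
  scr <- dominanceScreen(toy$truth, rates, dt = 1)
  expect_equal(scr$summary$distance[1], 0L)      # self-distance at low rate
  expect_gt(max(scr$summary$distance), 0L)       # dominance switches
  # low-rate dominant is the narrow high peak (chr1 = 6)
  expect_equal(parseKaryotype(scr$summary$dominant[1])[1], 6L)
  expect_true(all(abs(colSums(scr$steadyStates) - 1) < 1e-9))
  # flat landscape: self-distance zero at the lowest rate by construction
  ksf <- vapply(1:4, function(c1) kstr(kAlt(1, c1)), character(1L))
  scrF <- dominanceScreen(setNames(rep(0.5, 4), ksf), c(1e-4, 1e-2))
  expect_equal(scrF$summary$distance[1], 0L)
})

test_that("rate-response groups split by the sign of the correlation", {
  states <- vapply(1:3, function(c1) kstr(kAlt(1, c1)), character(1L))
  rates <- c(0.001, 0.01, 0.1)
  ss <- rbind(c(0.7, 0.5, 0.2),    # decreasing -> x
              c(0.2, 0.4, 0.7),    # increasing -> y
              c(0.1, 0.1, 0.1))    # constant -> unassigned
  rownames(ss) <- states
  g <- assignRateResponseGroups(ss, rates, topN = 3)
  expect_equal(g$group[match(states, g$karyotype)], c("x", "y", NA))
})
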