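#' Inference configuration
#'
#' @param minObs frequent-clone threshold: a karyotype is "frequent" if its
#'   summed count over all passages is at least `minObs`.
#' @param p missegregation probability assumed during inference (per copy per
#'   division). The default 0.00075 reflects typical literature averages for
#'   chromosomally unstable lines; inferred neighbor-fitness slopes are
#'   coupled to this value, so it is exposed rather than hidden.
#' @param muDelta,sigmaDelta mean and sd (per day) of the normal prior on the
#'   fitness difference between a neighbor and its frequent parent.
#' @param nugget observation-noise variance added to the Kriging diagonal
#'   (fitness^2 units).
#' @param radius charted-region radius in missegregation (Manhattan) steps.
#' @param nBoot bootstrap replicates for frequent-clone fitness CIs (0 = no
#'   bootstrap).
#' @param baseline absolute net growth rate (per day) assigned to the
#'   abundance-weighted population mean fitness at the first passage; only
#'   fitness differences are identified by the data.
#' @return An `inferenceConfig` list.
#' @export
inferenceConfig <- function(minObs = 10L, p = 0.00075, muDelta = 0,
                            sigmaDelta = 0.1, nugget = 1e-4, radius = 2L,
                            nBoot = 0L, baseline = 0.5) {
  stopifnot(minObs >= 1L, sigmaDelta > 0, radius >= 1L, nugget >= 0,
            p >= 0, p <= 0.5)
  structure(list(minObs = as.integer(minObs), p = p, muDelta = muDelta,
                 sigmaDelta = sigmaDelta, nugget = nugget,
                 radius = as.integer(radius), nBoot = as.integer(nBoot),
                 baseline = baseline),
            class = "inferenceConfig")
}

#' Identify frequent clones
#'
#' @param x a [KaryoCounts-class] object.
#' @param minObs minimum summed count across passages.
#' @return Character vector of frequent karyotype strings, ordered by
#'   decreasing total count.
#' @export
identifyFrequentClones <- function(x, minObs) {
  tot <- rowSums(countsMatrix(x))
  s <- names(sort(tot[tot >= minObs], decreasing = TRUE))
  if (!length(s))
    stop("no karyotype reaches minObs = ", minObs,
         "; lower the frequent-clone threshold")
  s
}

#' Closed-form solution of the continuous-time replicator equation
#'
#' For constant fitnesses the replicator equation
#' `dx_i/dt = x_i (f_i - sum_j x_j f_j)` has the closed form
#' `x_i(t) = x_i(0) exp(f_i t) / sum_j x_j(0) exp(f_j t)`; frequencies stay
#' on the simplex exactly.
#'
#' @param f fitness vector (per day).
#' @param x0 initial frequencies (must sum to 1 within 1e-8).
#' @param times evaluation times (days), relative to the `x0` timepoint.
#' @return Matrix of frequencies, `length(times)` rows x `length(f)` columns.
#' @export
replicatorSolution <- function(f, x0, times) {
  stopifnot(length(f) == length(x0), all(is.finite(f)), all(x0 >= 0))
  if (abs(sum(x0) - 1) > 1e-8)
    stop("x0 is off the simplex (sums to ", sum(x0), ")")
  out <- vapply(times, function(t) {
    w <- log(x0) + f * t
    w <- exp(w - max(w[is.finite(w)]))
    w / sum(w)
  }, numeric(length(f)))
  m <- if (is.matrix(out)) t(out) else matrix(out, ncol = 1L)
  colnames(m) <- names(f)
  m
}

# first-passage frequencies for the replicator initial condition; the +0.5
# continuity correction is applied only when some clone is unobserved there
firstPassageFreq <- function(cS) {
  c0 <- cS[, 1L]
  if (any(c0 == 0)) c0 <- c0 + 0.5
  c0 / sum(c0)
}

# Stage 1: weighted log-linear least squares, the exact solution of the
# convex QP "minimize sum_t sum_i w_it (log x_i(t) - log x_i(t0)
#  - (f_i - phi) (t - t0))^2 s.t. weighted-mean(f) = 0".
# Zero counts get a +0.5 continuity correction here only.
stage1Fit <- function(cnt, times, S) {
  n <- colSums(cnt)
  xhat <- sweep(cnt[S, , drop = FALSE] + 0.5, 2L, n + 0.5 * nrow(cnt), "/")
  dt <- times - times[1L]
  y <- log(xhat) - log(xhat[, 1L])
  w <- cnt[S, , drop = FALSE]
  slope <- vapply(seq_along(S), function(i) {
    ww <- w[i, ]
    num <- sum(ww * y[i, ] * dt)
    den <- sum(ww * dt^2)
    if (den == 0) 0 else num / den
  }, numeric(1L))
  names(slope) <- S
  tot <- rowSums(w)
  slope - sum(tot * slope) / sum(tot)  # identifiability: weighted mean 0
}

#' Estimate fitness of frequent clones from longitudinal counts
#'
#' Two-stage fit of the replicator model to the observed clone counts.
#' Stage 1 initializes fitness by weighted least squares on log-frequency
#' slopes versus time (count-weighted, +0.5 continuity correction for zero
#' counts, weighted-mean-zero identifiability constraint) -- the closed-form
#' solution of the corresponding convex quadratic program. Stage 2 refines
#' the estimates by maximizing the multinomial likelihood of the observed
#' counts under the closed-form replicator trajectories, with initial
#' frequencies fixed at the (continuity-corrected) first-passage
#' frequencies. Only fitness differences are identified; estimates are
#' returned centered (count-weighted mean zero) and are put on an absolute
#' scale by [growthOffsetCorrection()].
#'
#' @param x a [KaryoCounts-class] object (>= 2 passages).
#' @param S frequent-clone karyotypes (>= 2).
#' @param config an [inferenceConfig()].
#' @return List: `fitness` (named, centered), `stage1` (the initializer),
#'   `converged` logical, `logLik`.
#' @export
fitFrequentFitness <- function(x, S, config = inferenceConfig()) {
  stopifnot(length(S) >= 2L, ncol(x) >= 2L)
  fitFrequentCore(countsMatrix(x), passageTimes(x), S, config)
}

# two-stage fit on a bare count matrix (shared with the bootstrap)
fitFrequentCore <- function(cnt, times, S, config) {
  f1 <- stage1Fit(cnt, times, S)
  cS <- cnt[S, , drop = FALSE]
  nS <- colSums(cS)              # cells among S per passage
  x0 <- firstPassageFreq(cS)
  dt <- times - times[1L]
  negll <- function(fr) {
    f <- c(0, fr)
    xt <- replicatorSolution(f, x0, dt)
    xt <- pmax(xt, 1e-12)
    -sum(vapply(seq_along(dt), function(j)
      stats::dmultinom(cS[, j], prob = xt[j, ], log = TRUE), numeric(1L)))
  }
  # closed-form gradient: d(-ll)/df_i = sum_t t (n_t x_i(t) - c_it)
  gradll <- function(fr) {
    f <- c(0, fr)
    xt <- replicatorSolution(f, x0, dt)
    g <- colSums(dt * (nS * xt - t(cS)))
    g[-1L]
  }
  init <- f1 - f1[1L]
  opt <- try(stats::optim(init[-1L], negll, gr = gradll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-13)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0) {
    warning("stage-2 likelihood refinement did not converge; ",
            "returning stage-1 estimates")
    return(list(fitness = f1, stage1 = f1, converged = FALSE,
                logLik = NA_real_))
  }
  f <- c(0, opt$par)
  names(f) <- S
  tot <- rowSums(cS)
  f <- f - sum(tot * f) / sum(tot)
  list(fitness = f, stage1 = f1, converged = TRUE, logLik = -opt$value)
}

#' Shift relative fitness estimates to an absolute scale
#'
#' Replicator dynamics identify fitness only up to an additive constant. The
#' constant is fixed by requiring the abundance-weighted mean fitness at the
#' first passage to equal a declared baseline net growth rate. Pairwise
#' differences are unchanged.
#'
#' @param relativeF named fitness vector (karyotype strings).
#' @param x the [KaryoCounts-class] the fit came from.
#' @param baseline target mean net growth rate at the first passage
#'   (per day).
#' @return Shifted fitness vector.
#' @export
growthOffsetCorrection <- function(relativeF, x, baseline = 0.5) {
  w <- countsMatrix(x)[names(relativeF), 1L]
  if (sum(w) == 0) w <- rep(1, length(relativeF))
  relativeF + (baseline - sum(w * relativeF) / sum(w))
}

#' Bootstrap confidence intervals for frequent-clone fitness
#'
#' Cells are resampled within each passage (multinomial at the observed
#' frequencies, same depth) and the full two-stage estimator (QP
#' initialization + multinomial likelihood refinement) refit per replicate
#' -- resampling only the stage-1 initializer would summarize an estimator
#' whose systematic error the likelihood stage exists to remove. Because
#' only differences are identified, replicates are centered before
#' summarizing; percentile intervals for any pairwise difference can be
#' read from the returned sample matrix.
#'
#' @param x a [KaryoCounts-class] object.
#' @param S frequent clones.
#' @param config an [inferenceConfig()].
#' @param nBoot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level for the per-clone percentile CIs.
#' @return List: `samples` (nBoot x |S| matrix of centered fitness),
#'   `ci` data.frame (karyotype, lower, upper).
#' @export
bootstrapFitness <- function(x, S, config = inferenceConfig(), nBoot = 200L,
                             seed = 1L, level = 0.95) {
  stopifnot(nBoot >= 1L)
  cnt <- countsMatrix(x)
  times <- passageTimes(x)
  n <- colSums(cnt)
  withSeed(seed, {
    samples <- t(vapply(seq_len(nBoot), function(b) {
      bc <- vapply(seq_along(n), function(j)
        rmultinom(1L, n[j], cnt[, j])[, 1L], numeric(nrow(cnt)))
      rownames(bc) <- rownames(cnt)
      suppressWarnings(fitFrequentCore(bc, times, S, config)$fitness)
    }, numeric(length(S))))
    colnames(samples) <- S
    a <- (1 - level) / 2
    ci <- data.frame(karyotype = S,
                     lower = apply(samples, 2L, quantile, probs = a),
                     upper = apply(samples, 2L, quantile, probs = 1 - a),
                     row.names = NULL)
    list(samples = samples, ci = ci)
  })
}
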