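#' Estimate fitness of one-step neighbor karyotypes via mutational flux
#'
#' For each viable karyotype one missegregation away from the frequent set
#' S, the expected frequency trajectory is modeled as flux in from frequent
#' parents plus the neighbor's own (relative) growth:
#' `dx_i/dt = sum_{j in S} P(i|j) f_j x_j(t) + (f_i - phi(t)) x_i(t)`,
#' with `P(i|j)` the per-division missegregation transition probability at
#' the assumed rate `p`, parent trajectories `x_j(t)` from the fitted
#' replicator solution, and `phi(t) = sum_j f_j x_j(t)` the population mean
#' fitness -- the normalization that keeps frequencies on the simplex (the
#' bare growth form is the unnormalized shorthand of the same equation).
#' The linear ODE is solved by the integrating factor (trapezoidal
#' quadrature on a fine grid), and the neighbor fitness `f_i` maximizes the
#' binomial likelihood of the neighbor's observed counts plus a normal
#' prior `N(f_i - f_j | muDelta, sigmaDelta^2)` for each distance-1
#' frequent parent `j`. Absence of observations caps fitness: never-seen
#' neighbors get finite estimates pulled down by the binomial zero-count
#' term.
#'
#' @param x a [KaryoCounts-class] object.
#' @param freqFit named fitness vector for S (absolute scale, per day).
#' @param config an [inferenceConfig()]; `p` must be > 0.
#' @param gridN number of quadrature nodes on the observation interval.
#' @return data.frame: karyotype, fitness, nParents, observed (total count).
#' @export
fitNeighborFitness <- function(x, freqFit, config = inferenceConfig(),
                               gridN = 120L) {
  if (config$p <= 0) stop("neighbor fitness requires p > 0")
  S <- names(freqFit)
  cnt <- countsMatrix(x)
  times <- passageTimes(x)
  n <- colSums(cnt)
  tt <- times - times[1L]

  # parent frequency trajectories on a fine grid (replicator, within S);
  # the grid contains the observation times exactly
  cS <- cnt[S, , drop = FALSE]
  x0 <- firstPassageFreq(cS)
  grid <- sort(unique(c(seq(0, max(tt), length.out = gridN), tt)))
  xPar <- replicatorSolution(freqFit, x0, grid)      # gridN x |S|
  fluxBase <- sweep(xPar, 2L, freqFit, "*")          # f_j x_j(t)
  phi <- rowSums(fluxBase)                           # mean fitness phi(t)
  Phi <- cumtrapz(grid, phi)                         # integral of phi
  ttIdx <- match(tt, grid)
  PhiTT <- Phi[ttIdx]

  Smat <- karyoMatrix(S)
  nbs <- lapply(S, function(s) oneStepNeighbors(s, allowZero = FALSE))
  cand <- setdiff(unique(unlist(lapply(nbs, rownames))), S)
  if (!length(cand))
    return(data.frame(karyotype = character(0), fitness = numeric(0),
                      nParents = integer(0), observed = integer(0)))
  candMat <- karyoMatrix(cand)
  # per-division transition probabilities, parents (columns) -> candidates
  P <- vapply(seq_along(S), function(j)
    transitionProbMany(Smat[j, ], candMat, config$p), numeric(nrow(candMat)))
  if (!is.matrix(P)) P <- matrix(P, nrow = nrow(candMat))

  fLo <- min(freqFit) - 1
  fHi <- max(freqFit) + 1
  res <- lapply(seq_along(cand), function(ic) {
    key <- cand[ic]
    ki <- candMat[key, ]
    dPar <- manhattanDist(Smat, ki)
    adj <- which(dPar == 1L)
    if (!length(adj)) return(NULL)   # no distance-1 frequent parent: skip
    Pij <- P[ic, ]
    s_t <- as.numeric(fluxBase %*% Pij)              # influx on grid
    xi0 <- if (key %in% rownames(cnt)) cnt[key, 1L] / n[1L] else 0
    ci <- if (key %in% rownames(cnt)) cnt[key, ] else rep(0L, length(n))
    obj <- function(fi) {
      # integrating factor A(t) = fi*t - Phi(t);
      # x_i(t_k) = e^{A(t_k)+c} (xi0 e^{-c} + int_0^{t_k} e^{-A(tau)-c} s),
      # with the shift c = max(-A) keeping every exponent finite at extreme
      # trial fitnesses (overshooting trajectories clamp to 1 and are
      # rejected by the likelihood; underflows vanish harmlessly)
      A <- fi * grid - Phi
      Att <- fi * tt - PhiTT
      cshift <- max(-A)
      integ <- cumtrapz(grid, exp(-A - cshift) * s_t)[ttIdx]
      xi <- exp(pmin(Att + cshift, 700)) * (xi0 * exp(-cshift) + integ)
      xi <- pmin(pmax(xi, 1e-12), 1 - 1e-12)
      ll <- sum(dbinom(ci, n, xi, log = TRUE))
      ll + sum(dnorm(fi - freqFit[adj], config$muDelta, config$sigmaDelta,
                     log = TRUE))
    }
    opt <- optimize(obj, c(fLo, fHi), maximum = TRUE, tol = 1e-4)
    data.frame(karyotype = key, fitness = opt$maximum,
               nParents = length(adj), observed = sum(ci))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# cumulative trapezoid integral of y over x (same length, from x[1])
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

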