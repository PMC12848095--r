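#' Mean karyotype of a distribution
#'
#' Frequency-weighted mean copy number per chromosome; changes in this
#' 22-vector between timepoints are the population change vectors used by
#' the angle metric.
#'
#' @param dist named numeric vector: karyotype string -> relative frequency.
#' @return Numeric vector of length 22.
#' @export
meanKaryotype <- function(dist) {
  dist <- dist / sum(dist)
  km <- karyoMatrix(names(dist))
  as.numeric(colSums(km * dist))
}

#' Angle between two population change vectors
#'
#' Arc-cosine of the cosine similarity, in degrees: 0 means identical
#' evolutionary direction, 90 orthogonal, 180 opposite.
#'
#' @param vRef,vTest numeric 22-vectors (differences of mean karyotypes).
#' @return Angle in degrees in [0, 180]; `NaN` (with a warning) if either
#'   vector is zero, since a zero change has no direction.
#' @export
angleMetric <- function(vRef, vTest) {
  stopifnot(length(vRef) == length(vTest))
  nr <- sqrt(sum(vRef^2)); nt <- sqrt(sum(vTest^2))
  if (nr == 0 || nt == 0) {
    warning("zero change vector: angle undefined")
    return(NaN)
  }
  cs <- sum(vRef * vTest) / (nr * nt)
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Monte Carlo test of directional consistency against the random null
#'
#' Observed angles are grouped by experimental unit; the global statistic T
#' is the median of the per-unit medians. Under the null, angles are those
#' between independent 22-D standard-Gaussian unit vectors; each of `nIter`
#' iterations draws matched-size synthetic angle sets per unit and
#' recomputes T*. The one-sided p-value is the proportion of T* less than
#' or equal to the observed T (smaller angles = more aligned than random);
#' the two-sided p doubles the smaller tail (capped at 1).
#'
#' @param perUnitAngles list of numeric vectors of angles (degrees), one
#'   vector per unit.
#' @param alternative "one" (alignment) or "two" sided.
#' @param nIter Monte Carlo iterations.
#' @param seed RNG seed.
#' @return List: `T_obs` (degrees), `p_value`, `n_iter`, `null_T` samples.
#' @export
angleNullTest <- function(perUnitAngles, alternative = c("one", "two"),
                          nIter = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  if (!length(perUnitAngles) ||
      any(!vapply(perUnitAngles, length, integer(1L))))
    stop("each unit needs at least one angle")
  sizes <- vapply(perUnitAngles, length, integer(1L))
  Tobs <- median(vapply(perUnitAngles, median, numeric(1L)))
  total <- sum(sizes)
  grp <- rep.int(seq_along(sizes), sizes)
  Tstar <- withSeed(seed, vapply(seq_len(nIter), function(i) {
    ang <- randomNullAngles(total)
    median(vapply(split(ang, grp), median, numeric(1L)))
  }, numeric(1L)))
  lo <- mean(Tstar <= Tobs)
  p <- if (alternative == "one") lo else min(1, 2 * min(lo, mean(Tstar >= Tobs)))
  list(T_obs = Tobs, p_value = p, n_iter = nIter, null_T = Tstar)
}

# angles (degrees) between pairs of independent uniform unit vectors in 22-D
randomNullAngles <- function(n) {
  u <- matrix(rnorm(n * N_AUTOSOMES), n)
  v <- matrix(rnorm(n * N_AUTOSOMES), n)
  cs <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Static no-evolution baseline forecast
#'
#' The baseline prediction is simply the last observed karyotype
#' distribution, unchanged.
#'
#' @param last named frequency vector.
#' @return The same distribution.
#' @export
noEvolutionBaseline <- function(last) last / sum(last)

#' Abundance overlap coefficient between two distributions
#'
#' `sum_k min(d1(k), d2(k))`: 1 for identical distributions, 0 for disjoint
#' supports. Lower overlap between consecutive passages signals larger
#' compositional shifts.
#'
#' @param d1,d2 named frequency vectors.
#' @return Scalar in [0, 1].
#' @export
overlapCoefficient <- function(d1, d2) {
  d1 <- d1 / sum(d1); d2 <- d2 / sum(d2)
  ks <- union(names(d1), names(d2))
  g1 <- setNames(numeric(length(ks)), ks); g1[names(d1)] <- d1
  g2 <- setNames(numeric(length(ks)), ks); g2[names(d2)] <- d2
  sum(pmin(g1, g2))
}

#' Forecast a future karyotype distribution from a fitted landscape
#'
#' Seeds an agent-based population proportional to `start`, runs it forward
#' on the landscape's look-up table for `horizonDays`, and averages the
#' resulting frequency distributions over `nReplicates` independent runs.
#' Karyotypes leaving the charted region are handled by the look-up-table
#' policy (lethal by default).
#'
#' @param landscape a [FittedLandscape-class] or [LUTLandscape-class].
#' @param start named frequency vector (supported inside the LUT).
#' @param horizonDays forecast horizon in days (0 returns `start`).
#' @param nReplicates independent simulation replicates to average.
#' @param seed RNG seed.
#' @param p missegregation probability during forward simulation (defaults
#'   to the fitted configuration's `p` when available).
#' @param nCells cells seeded per replicate.
#' @param dt simulation time step (days).
#' @param policy out-of-table policy when `landscape` is a FittedLandscape.
#' @return Named frequency vector of the replicate-averaged forecast.
#' @export
forecastPopulation <- function(landscape, start, horizonDays,
                               nReplicates = 3L, seed = 1L, p = NULL,
                               nCells = 2000L, dt = 0.1,
                               policy = "lethal") {
  start <- start / sum(start)
  if (horizonDays == 0) return(start)
  lut <- if (methods::is(landscape, "FittedLandscape")) {
    if (is.null(p)) p <- landscape@config$p
    LUTLandscape(setNames(landscape@lut$mean_fitness,
                          landscape@lut$karyotype), policy = policy)
  } else landscape
  if (is.null(p)) stop("p must be given for a bare LUT landscape")
  fmax <- max(abs(lut@table))
  if (fmax * dt >= 1) dt <- 0.5 / fmax
  acc <- list()
  for (r in seq_len(nReplicates)) {
    cfg <- simConfig(p = p, nMax = 10 * nCells, nSeed = nCells, dt = dt,
                     tEnd = horizonDays,
                     founder = setNames(
                       as.integer(rmultinomSeed(seed * 1000L + r, nCells,
                                                start)), names(start)),
                     sampleSize = nCells, sampleTimes = numeric(0),
                     seed = seed * 1000L + r)
    sim <- runSimulation(lut, cfg)
    fin <- sim$finalState$counts
    if (sum(fin) > 0) acc[[length(acc) + 1L]] <- fin / sum(fin)
  }
  if (!length(acc)) stop("all forecast replicates went extinct")
  ks <- unique(unlist(lapply(acc, names)))
  avg <- setNames(numeric(length(ks)), ks)
  for (d in acc) avg[names(d)] <- avg[names(d)] + d / length(acc)
  avg[avg > 0]
}

rmultinomSeed <- function(seed, n, prob) {
  withSeed(seed, rmultinom(1L, n, prob)[, 1L])
}

#' Fraction of forecasts beating the no-evolution baseline
#'
#' @param predictionMetric,baselineMetric paired numeric vectors of a
#'   "smaller is better" metric (e.g. Wasserstein distance to the realized
#'   next passage, or angle to the realized change).
#' @return Fraction of pairs where the prediction is strictly better; ties
#'   do not count as beating the baseline.
#' @export
beatBaselineFraction <- function(predictionMetric, baselineMetric) {
  stopifnot(length(predictionMetric) == length(baselineMetric))
  if (!length(predictionMetric)) stop("no paired records")
  mean(predictionMetric < baselineMetric)
}
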