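#' Run one synthetic ground-truth validation replicate
#'
#' Executes the full validation loop on a GRF fixture: simulate serial
#' passaging on a known Gaussian-random-field landscape, fit the local
#' fitness landscape from the training window (with the CV-maximizing
#' frequent-clone threshold), score the fit against ground truth
#' (Spearman correlation over the charted region), forecast the next
#' observed passage, and compare the forecast's Wasserstein distance to
#' the realized sample against the static no-evolution baseline.
#'
#' @param seed integer seed controlling the fixture (landscape + ABM run).
#' @param scenario `"smooth_grf"` or `"rugged_grf"`.
#' @param minObsGrid frequent-clone thresholds swept by CV score.
#' @param forecastReplicates ABM replicates averaged into the forecast.
#' @param supportCap distributions are truncated to this many most-frequent
#'   karyotypes (renormalized) before the exact optimal-transport solve.
#' @return One-row data.frame: seed, cv, spearman (LUT vs truth),
#'   wassersteinForecast, wassersteinBaseline, beatsBaseline, minObs,
#'   horizonDays, nLut.
#' @seealso [generateFixture()], [fitKaryotypeLandscape()],
#'   [forecastPopulation()]
#' @export
validateSyntheticRun <- function(seed, scenario = "smooth_grf",
                                 minObsGrid = c(10L, 20L, 40L),
                                 forecastReplicates = 3L,
                                 supportCap = 150L) {
  fx <- generateFixture(scenario, seed = seed)
  fit <- suppressWarnings(
    fitKaryotypeLandscape(fx$counts, inferenceConfig(),
                          minObsGrid = minObsGrid, lutSd = FALSE))
  lut <- landscapeLUT(fit)
  sp <- cor(lut$mean_fitness, fitnessOf(fx$truth, lut$karyotype),
            method = "spearman")
  t0 <- max(fx$trainTimes)
  t1 <- fx$futureTimes[1L]
  start <- sampleDistributionAt(fx$allSamples, t0)
  realized <- sampleDistributionAt(fx$allSamples, t1)
  fc <- forecastPopulation(fit, start, horizonDays = t1 - t0,
                           nReplicates = forecastReplicates, seed = seed,
                           p = fx$sim$config$p)
  wPred <- wassersteinDist(truncateSupport(fc, supportCap),
                           truncateSupport(realized, supportCap))
  wBase <- wassersteinDist(truncateSupport(start, supportCap),
                           truncateSupport(realized, supportCap))
  data.frame(seed = seed, cv = cvScoreOf(fit), spearman = sp,
             wassersteinForecast = wPred, wassersteinBaseline = wBase,
             beatsBaseline = wPred < wBase,
             minObs = fit@config$minObs, horizonDays = t1 - t0,
             nLut = nrow(lut))
}

#' @describeIn validateSyntheticRun run several replicates and bind rows.
#' @param seeds integer vector of replicate seeds.
#' @param ... passed on to `validateSyntheticRun`.
#' @export
syntheticValidation <- function(seeds, ...) {
  do.call(rbind, lapply(seeds, function(s) validateSyntheticRun(s, ...)))
}

# frequency distribution of the recorded sample closest to time t
sampleDistributionAt <- function(samples, t) {
  df <- samples[abs(samples$time_days - t) < 1e-9, , drop = FALSE]
  if (!nrow(df)) stop("no recorded sample at day ", t)
  setNames(df$count / sum(df$count), df$karyotype)
}

# keep the n most frequent karyotypes and renormalize
truncateSupport <- function(d, n) {
  d <- sort(d, decreasing = TRUE)
  d <- d[seq_len(min(n, length(d)))]
  d / sum(d)
}
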