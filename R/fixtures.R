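#' Generate a named synthetic dataset preset
#'
#' Runs the ground-truth landscape + agent-based simulation pipeline with
#' frozen preset parameters and returns everything needed to train and
#' score the inference: longitudinal counts, the true landscape, and a
#' manifest. Presets:
#' \describe{
#'   \item{smooth_grf}{Gaussian random field with long wavelength
#'     (lambda = 2), missegregation p = 0.002/copy/division, capacity 1e4,
#'     reseed 1e3, 500-cell samples at every passage over 150 days. The
#'     manifest marks the 8 consecutive passages ending nearest day 120 as
#'     the training window.}
#'   \item{rugged_grf}{As smooth_grf but lambda = 0.4 (rugged terrain).}
#'   \item{two_clone}{Two karyotypes (diploid and diploid +chr1) with
#'     fitness 0.5 and 0.6/day, p = 0: pure replicator competition.}
#'   \item{flat_neutral}{Constant fitness 0.5/day, p = 0.002: neutral
#'     missegregation accumulation.}
#'   \item{two_peak_toy}{A one-chromosome-axis look-up table (chr1 copies
#'     1..8, all other chromosomes diploid) with a narrow high peak
#'     (copy 6, 1.0/day) against a broad lower plateau (copies 1-3,
#'     0.8/day): exhibits an error-threshold dominance switch.}
#' }
#'
#' @param scenario preset name.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param dir optional directory: writes `counts.csv`, `truth.csv`
#'   (karyotype, true_fitness over the charted region of the training
#'   frequent set where applicable) and `manifest.json`.
#' @return List: `scenario`, `seed`, `counts` ([KaryoCounts-class], training
#'   window), `allSamples` (data.frame of every recorded sample),
#'   `trainTimes`, `futureTimes`, `truth` (landscape object), `sim`
#'   (`karyoSim`, when simulated), `manifest`.
#' @export
generateFixture <- function(scenario, seed = 1L, dir = NULL) {
  presets <- c("smooth_grf", "rugged_grf", "two_clone", "flat_neutral",
               "two_peak_toy")
  if (!scenario %in% presets)
    stop("unknown scenario '", scenario, "'; presets: ",
         paste(presets, collapse = ", "))
  diploid <- formatKaryotype(rep(2L, N_AUTOSOMES))
  out <- switch(scenario,
    smooth_grf = grfFixture(2.0, seed),
    rugged_grf = grfFixture(0.4, seed),
    two_clone = {
      k2 <- formatKaryotype(c(3L, rep(2L, N_AUTOSOMES - 1L)))
      truth <- LUTLandscape(setNames(c(0.5, 0.6), c(diploid, k2)))
      cfg <- simConfig(p = 0, nMax = 1e4, nSeed = 1e3, dt = 0.1, tEnd = 60,
                       founder = setNames(c(500L, 500L), c(diploid, k2)),
                       sampleSize = 500L, seed = seed)
      sim <- runSimulation(truth, cfg)
      list(counts = asKaryoCounts(sim), allSamples = sim$samples,
           trainTimes = sort(unique(sim$samples$time_days)),
           futureTimes = numeric(0), truth = truth, sim = sim)
    },
    flat_neutral = {
      truth <- function(k) rep(0.5, nrow(k))
      cfg <- simConfig(p = 0.002, nMax = 1e4, nSeed = 1e3, dt = 0.1,
                       tEnd = 100, founder = diploid, sampleSize = 500L,
                       seed = seed)
      sim <- runSimulation(truth, cfg)
      list(counts = asKaryoCounts(sim), allSamples = sim$samples,
           trainTimes = sort(unique(sim$samples$time_days)),
           futureTimes = numeric(0), truth = truth, sim = sim)
    },
    two_peak_toy = {
      ks <- vapply(1:8, function(c1)
        formatKaryotype(c(c1, rep(2L, N_AUTOSOMES - 1L))), character(1L))
      f <- c(0.8, 0.8, 0.8, 0.2, 0.1, 1.0, 0.1, 0.1)
      list(counts = NULL, allSamples = NULL, trainTimes = numeric(0),
           futureTimes = numeric(0),
           truth = LUTLandscape(setNames(f, ks)), sim = NULL)
    })
  manifest <- list(scenario = scenario, seed = seed,
                   trainTimes = out$trainTimes,
                   futureTimes = out$futureTimes,
                   generator = "karyofit::generateFixture")
  out <- c(out, list(scenario = scenario, seed = seed, manifest = manifest))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$counts))
      writeKaryoCounts(out$counts, file.path(dir, "counts.csv"))
    if (methods::is(out$truth, "LUTLandscape")) {
      write.csv(data.frame(karyotype = names(out$truth@table),
                           true_fitness = unname(out$truth@table)),
                file.path(dir, "truth.csv"), row.names = FALSE,
                quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# GRF + ABM fixture shared by smooth_grf / rugged_grf: serial passaging on a
# frozen random landscape, observed by 500-cell samples every 15 days (the
# typical experimental passage-to-sequencing cadence); the 8 samples at days
# 15..120 form the training window, later samples are forecasting targets.
grfFixture <- function(wavelength, seed, nTrain = 8L, obsGap = 15,
                       tEnd = 150) {
  truth <- grfLandscape(wavelength = wavelength, nBasis = 60L,
                        amplitude = 0.3, offset = 0.5, seed = seed)
  obs <- seq(obsGap, tEnd, by = obsGap)
  cfg <- simConfig(p = 0.002, nMax = 1e4, nSeed = 1e3, dt = 0.1, tEnd = tEnd,
                   founder = formatKaryotype(rep(2L, N_AUTOSOMES)),
                   sampleSize = 500L, sampleTimes = obs,
                   seed = seed + 10000L)
  sim <- runSimulation(truth, cfg)
  got <- sort(unique(sim$samples$time_days))
  obs <- obs[obs %in% got]
  if (length(obs) < 2L) stop("simulation produced too few observations")
  trainTimes <- head(obs, nTrain)
  futureTimes <- obs[obs > max(trainTimes)]
  list(counts = asKaryoCounts(sim, times = trainTimes),
       allSamples = sim$samples, trainTimes = trainTimes,
       futureTimes = futureTimes, truth = truth, sim = sim)
}
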