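#' Fit a local karyotype fitness landscape from longitudinal counts
#'
#' Full inference pipeline: (1) identify frequent clones; (2) estimate their
#' fitness from replicator dynamics (QP-initialized multinomial maximum
#' likelihood); (3) put estimates on an absolute scale via the growth-offset
#' correction; (4) extend fitness to one-missegregation-step neighbors via
#' the mutational-flux model; (5) interpolate over the charted region
#' (within `radius` missegregations of the frequent set) with Matern-3/2
#' Kriging; (6) compute the leave-one-out CV score over the frequent
#' anchors as an internal consistency check. Deterministic given the data
#' and configuration.
#'
#' When `minObsGrid` is supplied, the pipeline is run once per candidate
#' frequent-clone threshold and the fit with the highest CV score is kept --
#' the threshold is a model-selection knob and the CV score its selection
#' criterion.
#'
#' @param x a [KaryoCounts-class] object.
#' @param config an [inferenceConfig()].
#' @param minObsGrid optional integer vector of thresholds to sweep
#'   (overrides `config$minObs`).
#' @param lutSd compute predictive standard deviations for the look-up
#'   table (one triangular solve per karyotype; disable for speed when only
#'   mean fitness is needed).
#' @return A [FittedLandscape-class] object.
#' @examples
#' \dontrun{
#' fit <- fitKaryotypeLandscape(counts, inferenceConfig(minObs = 10))
#' head(landscapeLUT(fit)); cvScoreOf(fit)
#' }
#' @export
fitKaryotypeLandscape <- function(x, config = inferenceConfig(),
                                  minObsGrid = NULL, lutSd = TRUE) {
  if (is.null(minObsGrid)) minObsGrid <- config$minObs
  fits <- list()
  for (mo in minObsGrid) {
    cfg <- config
    cfg$minObs <- as.integer(mo)
    f <- tryCatch(fitAnchors(x, cfg), error = function(e) e)
    if (!inherits(f, "error")) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    # re-raise the staged error from the single (or last) configuration
    cfg <- config
    cfg$minObs <- as.integer(minObsGrid[length(minObsGrid)])
    fitAnchors(x, cfg)
  }
  cvs <- vapply(fits, function(f) f$cv, numeric(1L))
  best <- fits[[which.max(replace(cvs, is.nan(cvs), -Inf))]]
  buildLandscape(best, lutSd = lutSd)
}

# stages 1-4 + GP + CV for one configuration (no look-up table yet)
fitAnchors <- function(x, config) {
  stage <- "frequent-clone identification"
  tryCatch({
    S <- identifyFrequentClones(x, config$minObs)
    stage <- "frequent-clone fitness estimation"
    ff <- fitFrequentFitness(x, S, config)
    fS <- growthOffsetCorrection(ff$fitness, x, config$baseline)
    stage <- "neighbor fitness estimation"
    nb <- fitNeighborFitness(x, fS, config)
    anchors <- rbind(
      data.frame(karyotype = names(fS), fitness = unname(fS),
                 source = "frequent"),
      data.frame(karyotype = nb$karyotype, fitness = nb$fitness,
                 source = "neighbor"))
    stage <- "Kriging interpolation"
    gp <- fitKriging(anchors$karyotype, anchors$fitness,
                     nugget = config$nugget)
    stage <- "cross-validation"
    cv <- cvScore(anchors$karyotype, anchors$fitness,
                  frequentIdx = which(anchors$source == "frequent"),
                  nugget = config$nugget, model = gp)
    list(S = S, anchors = anchors, gp = gp, cv = cv, config = config)
  }, error = function(e) {
    stop("landscape fit failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
}

buildLandscape <- function(fit, lutSd = TRUE) {
  region <- chartedRegion(fit$S, fit$config$radius)
  pred <- predictKriging(fit$gp, region, computeSd = lutSd)
  nbk <- fit$anchors$karyotype[fit$anchors$source == "neighbor"]
  src <- rep("interpolated", length(region))
  src[region %in% nbk] <- "neighbor"
  src[region %in% fit$S] <- "frequent"
  lut <- data.frame(karyotype = region, mean_fitness = pred$mean,
                    sd = pred$sd, source = src)
  methods::new("FittedLandscape", frequent = fit$S, anchors = fit$anchors,
               gp = unclass(fit$gp), lut = lut, cvScore = fit$cv,
               config = unclass(fit$config))
}
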