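#' Generate a Gaussian-random-field fitness landscape
#'
#' Random plane-wave (random-Fourier-feature) synthesis over 22-D
#' copy-number space: `nBasis` sinusoids with uniform random unit directions
#' and phases, characteristic wavelength `wavelength` (Euclidean copy-number
#' units). As `nBasis` grows the marginal law of `f(k) - offset` at any fixed
#' `k` tends to Gaussian with variance `amplitude^2 / 2`; larger wavelengths
#' give smoother landscapes (higher fitness correlation between neighboring
#' karyotypes). Defaults put the founder diploid near 0.5 divisions/day net
#' growth with fluctuations of standard deviation ~0.2/day, a realistic
#' in-vitro scale.
#'
#' @param wavelength characteristic wavelength lambda > 0.
#' @param nBasis number of plane-wave components.
#' @param amplitude overall fitness fluctuation scale (per day).
#' @param offset mean fitness level (per day).
#' @param seed integer RNG seed; the landscape is frozen and fully
#'   reproducible from `(seed, wavelength, nBasis, amplitude, offset)`.
#' @return A [GRFLandscape-class] object; evaluate with [fitnessOf()].
#' @examples
#' g <- grfLandscape(wavelength = 1.6, seed = 1)
#' fitnessOf(g, formatKaryotype(rep(2L, 22)))
#' @export
grfLandscape <- function(wavelength, nBasis = 60L, amplitude = 0.3,
                         offset = 0.5, seed = 1L) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  stopifnot(nBasis >= 1L)
  comp <- withSeed(seed, {
    u <- matrix(rnorm(nBasis * N_AUTOSOMES), nBasis, N_AUTOSOMES)
    u <- u / sqrt(rowSums(u^2))
    list(directions = u, phases = runif(nBasis, 0, 2 * pi))
  })
  methods::new("GRFLandscape", wavelength = as.numeric(wavelength),
               amplitude = as.numeric(amplitude), offset = as.numeric(offset),
               nBasis = as.integer(nBasis), seed = as.integer(seed),
               directions = comp$directions, phases = comp$phases)
}

#' Serialize / restore a GRF landscape specification
#'
#' Only the generation parameters are stored; the landscape is rebuilt
#' deterministically from them, so a config line fully reproduces any
#' simulation.
#'
#' @param x a [GRFLandscape-class].
#' @return `grfSpec`: named list; `grfFromSpec`: the rebuilt landscape.
#' @export
grfSpec <- function(x) {
  list(wavelength = x@wavelength, nBasis = x@nBasis,
       amplitude = x@amplitude, offset = x@offset, seed = x@seed)
}

#' @rdname grfSpec
#' @param spec named list as returned by `grfSpec`.
#' @export
grfFromSpec <- function(spec) {
  grfLandscape(spec$wavelength, spec$nBasis, spec$amplitude, spec$offset,
               spec$seed)
}
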