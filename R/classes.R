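#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median optim optimize rbinom rnorm runif rmultinom
#'   setNames sd var cor dbinom dnorm quantile complete.cases aggregate
#' @importFrom utils head read.csv write.csv
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Longitudinal karyotype counts
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one `counts` assay: rows are karyotypes (rownames are dot-separated
#' copy-number strings), columns are passages, and `colData` carries the
#' observation time in days (`time_days`, strictly increasing).
#'
#' @slot \dots see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("KaryoCounts", contains = "SummarizedExperiment")

setValidity("KaryoCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m))) return("karyotype rownames are required")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!"time_days" %in% colnames(cd)) return("colData needs a time_days column")
  t <- cd$time_days
  if (any(diff(t) <= 0)) return("passage times must be strictly increasing")
  ok <- vapply(rownames(m), function(s)
    !inherits(try(parseKaryotype(s), silent = TRUE), "try-error"), logical(1L))
  if (!all(ok)) return(paste0("invalid karyotype rowname: ",
                              rownames(m)[which(!ok)[1L]]))
  TRUE
})

#' Construct a KaryoCounts object
#'
#' @param counts integer matrix, karyotypes (rownames, dot-separated strings)
#'   by passages.
#' @param timeDays numeric vector of passage times in days, strictly
#'   increasing, one per column.
#' @return A [KaryoCounts-class] object.
#' @export
KaryoCounts <- function(counts, timeDays) {
  stopifnot(ncol(counts) == length(timeDays))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("passage_", seq_along(timeDays))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(time_days = as.numeric(timeDays)))
  methods::new("KaryoCounts", se)
}

#' @describeIn KaryoCounts passage times in days.
#' @param x a `KaryoCounts` object.
#' @export
passageTimes <- function(x) SummarizedExperiment::colData(x)$time_days

#' @describeIn KaryoCounts karyotype strings (rownames).
#' @export
karyotypes <- function(x) rownames(x)

#' @describeIn KaryoCounts the karyotype x passage count matrix.
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn KaryoCounts total cells per passage.
#' @export
totalCells <- function(x) colSums(countsMatrix(x))

setMethod("show", "KaryoCounts", function(object) {
  cat("KaryoCounts:", nrow(object), "karyotypes x", ncol(object),
      "passages\n")
  cat("  days:", paste(signif(passageTimes(object), 4), collapse = ", "),
      "\n")
  cat("  cells/passage:", paste(totalCells(object), collapse = ", "), "\n")
})

#' Evaluate fitness of karyotypes under a landscape
#'
#' @param object a landscape ([GRFLandscape-class], [LUTLandscape-class],
#'   [FittedLandscape-class]) or a plain function of a karyotype matrix.
#' @param k karyotype string(s) or an integer matrix (one karyotype per row).
#' @param ... passed to methods.
#' @return Numeric fitness (net growth rate, per day), one value per
#'   karyotype; `NA` marks karyotypes the landscape declares nonviable
#'   (lethal look-up-table policy).
#' @export
setGeneric("fitnessOf", function(object, k, ...) standardGeneric("fitnessOf"))

#' Gaussian-random-field fitness landscape
#'
#' Ground-truth synthetic landscape built by random plane-wave synthesis:
#' `f(k) = offset + amplitude/sqrt(nBasis) * sum_j sin(2*pi*<k, u_j>/lambda
#' + phi_j)` with `u_j` uniform unit directions in 22-D and phases
#' `phi_j ~ U(0, 2*pi)`. The characteristic wavelength `lambda` (Euclidean
#' units in copy-number space) controls smoothness: larger `lambda`, smoother
#' terrain. Deterministic given `(seed, lambda, nBasis)`.
#'
#' @slot wavelength,amplitude,offset,nBasis,seed generation parameters.
#' @slot directions,phases the frozen random components.
#' @export
setClass("GRFLandscape",
  representation(wavelength = "numeric", amplitude = "numeric",
                 offset = "numeric", nBasis = "integer", seed = "integer",
                 directions = "matrix", phases = "numeric"))

setValidity("GRFLandscape", function(object) {
  if (object@wavelength <= 0) return("wavelength must be > 0")
  if (object@nBasis < 1L) return("nBasis must be >= 1")
  if (nrow(object@directions) != object@nBasis ||
      length(object@phases) != object@nBasis)
    return("component dimensions inconsistent with nBasis")
  TRUE
})

#' Look-up-table fitness landscape
#'
#' A finite karyotype -> fitness map with a total out-of-table policy:
#' `"lethal"` (karyotypes outside the table are nonviable, fitness `NA`),
#' `"min_fitness"` (they get the minimum tabled fitness), or
#' `"nearest_anchor"` (fitness of the nearest tabled karyotype by Manhattan
#' distance, smallest index on ties).
#'
#' @slot table named numeric vector (names = karyotype strings).
#' @slot policy character, one of the three policies above.
#' @export
setClass("LUTLandscape",
  representation(table = "numeric", policy = "character"))

setValidity("LUTLandscape", function(object) {
  if (is.null(names(object@table)) || !length(object@table))
    return("table must be a non-empty named numeric vector")
  if (any(!is.finite(object@table))) return("fitness values must be finite")
  if (!object@policy %in% c("lethal", "min_fitness", "nearest_anchor"))
    return("unknown out-of-table policy")
  TRUE
})

#' @rdname LUTLandscape-class
#' @param table named numeric vector of fitness values (per day).
#' @param policy out-of-table policy.
#' @export
LUTLandscape <- function(table, policy = c("lethal", "min_fitness",
                                           "nearest_anchor")) {
  methods::new("LUTLandscape", table = table, policy = match.arg(policy))
}

#' Fitted local karyotype fitness landscape
#'
#' Result of the full inference pipeline: fitness anchors for frequent
#' clones and their one-step neighbors, a frozen Matern-3/2 Gaussian-process
#' (Kriging) interpolator, a fitness look-up table covering the charted
#' region, and the leave-one-out cross-validation score (max 1, can be
#' negative; higher means better internal consistency).
#'
#' @slot frequent karyotype strings of the frequent-clone set S.
#' @slot anchors data.frame: karyotype, fitness, source ("frequent" or
#'   "neighbor").
#' @slot gp frozen Kriging model (list, see [fitKriging()]).
#' @slot lut data.frame over the charted region: karyotype, mean_fitness,
#'   sd, source ("frequent", "neighbor" or "interpolated").
#' @slot cvScore leave-one-out predictive R^2 over frequent anchors.
#' @slot config the [inferenceConfig()] used.
#' @export
setClass("FittedLandscape",
  representation(frequent = "character", anchors = "data.frame",
                 gp = "listOrNULL", lut = "data.frame", cvScore = "numeric",
                 config = "list"))

setValidity("FittedLandscape", function(object) {
  need <- c("karyotype", "mean_fitness", "sd", "source")
  if (!all(need %in% colnames(object@lut)))
    return("lut must have karyotype, mean_fitness, sd, source columns")
  if (!all(object@frequent %in% object@anchors$karyotype))
    return("every frequent karyotype needs an anchor fitness")
  if (length(object@cvScore) != 1L) return("cvScore must be scalar")
  TRUE
})

setMethod("show", "GRFLandscape", function(object) {
  cat("GRFLandscape: lambda =", object@wavelength, ", nBasis =",
      object@nBasis, ", amplitude =", object@amplitude, ", offset =",
      object@offset, ", seed =", object@seed, "\n")
})

setMethod("show", "LUTLandscape", function(object) {
  cat("LUTLandscape:", length(object@table), "karyotypes, policy =",
      object@policy, "\n")
  cat("  fitness range: [", signif(min(object@table), 4), ",",
      signif(max(object@table), 4), "] per day\n")
})

setMethod("show", "FittedLandscape", function(object) {
  cat("FittedLandscape:", length(object@frequent), "frequent clones,",
      sum(object@anchors$source == "neighbor"), "neighbor anchors,",
      nrow(object@lut), "karyotypes in charted region\n")
  cat("  CV score:", signif(object@cvScore, 4), "\n")
})

#' @describeIn FittedLandscape the charted-region look-up table.
#' @param x a `FittedLandscape`.
#' @export
landscapeLUT <- function(x) x@lut

#' @describeIn FittedLandscape leave-one-out CV score.
#' @export
cvScoreOf <- function(x) x@cvScore

#' @describeIn FittedLandscape frequent-clone karyotypes.
#' @export
frequentClones <- function(x) x@frequent

#' @describeIn FittedLandscape anchor table (frequent + neighbor fitness).
#' @export
anchorTable <- function(x) x@anchors

#' @rdname fitnessOf
setMethod("fitnessOf", "GRFLandscape", function(object, k, ...) {
  if (is.character(k)) k <- karyoMatrix(k)
  if (!is.matrix(k)) k <- matrix(k, nrow = 1L)
  s <- (2 * pi / object@wavelength) * (k %*% t(object@directions))
  s <- sweep(s, 2L, object@phases, "+")
  unname(drop(object@offset + object@amplitude / sqrt(object@nBasis) *
                rowSums(sin(s))))
})

#' @rdname fitnessOf
setMethod("fitnessOf", "LUTLandscape", function(object, k, ...) {
  keys <- if (is.matrix(k)) formatKaryotype(k) else as.character(k)
  f <- unname(object@table[keys])
  miss <- is.na(f)
  if (any(miss)) {
    f[miss] <- switch(object@policy,
      lethal = NA_real_,
      min_fitness = min(object@table),
      nearest_anchor = {
        anchors <- karyoMatrix(names(object@table))
        vapply(keys[miss], function(s) {
          d <- manhattanDist(anchors, parseKaryotype(s))
          object@table[[which.min(d)]]
        }, numeric(1L))
      })
  }
  f
})

#' @rdname fitnessOf
setMethod("fitnessOf", "FittedLandscape", function(object, k, ...) {
  tab <- setNames(object@lut$mean_fitness, object@lut$karyotype)
  keys <- if (is.matrix(k)) formatKaryotype(k) else as.character(k)
  unname(tab[keys])
})

#' @rdname fitnessOf
setMethod("fitnessOf", "function", function(object, k, ...) {
  if (is.character(k)) k <- karyoMatrix(k)
  if (!is.matrix(k)) k <- matrix(k, nrow = 1L)
  object(k)
})

# Evaluate an expression with a temporary RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
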