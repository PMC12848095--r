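#' Simulation configuration for the agent-based model
#'
#' The ABM tracks a population of cells as a karyotype -> count map. Each
#' time step of length `dt` days, a cell of fitness `f >= 0` divides with
#' probability `f * dt` (binomial thinning); each division replaces the cell
#' by two daughters whose karyotypes follow the per-copy missegregation
#' kernel at rate `p`. Negative fitness acts as a death rate (`|f| * dt`
#' death probability). Daughters with a zero-copy chromosome die immediately,
#' as do daughters falling outside a lethal-policy look-up table. Whenever
#' the population reaches `nMax` cells it is passaged: multinomially
#' down-sampled to `nSeed` cells, emulating serial transfer, and a
#' `sampleSize`-cell multinomial sample (emulating single-cell sequencing of
#' the harvested material) is recorded.
#'
#' @param p per-copy missegregation probability per division, in [0, 0.5].
#' @param nMax passaging capacity (cells).
#' @param nSeed cells re-seeded after each passage (default `nMax / 10`).
#' @param dt time step, days. Must satisfy `|f| * dt < 1` for all fitnesses.
#' @param tEnd total simulated time, days.
#' @param founder founder karyotype string, or a named count vector for a
#'   mixed initial population (counts are used as-is).
#' @param sampleSize cells per recorded observation.
#' @param sampleTimes extra observation days (samples are always recorded at
#'   passage events).
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return A `simConfig` list.
#' @export
simConfig <- function(p = 0.002, nMax = 1e4, nSeed = NULL, dt = 0.1,
                      tEnd = 150, founder = formatKaryotype(rep(2L, 22)),
                      sampleSize = 500L, sampleTimes = numeric(0),
                      seed = 1L) {
  if (p < 0 || p > 0.5) stop("p must be in [0, 0.5]")
  if (is.null(nSeed)) nSeed <- max(1L, round(nMax / 10))
  if (nSeed <= 0 || nSeed > nMax) stop("require 0 < nSeed <= nMax")
  if (dt <= 0) stop("dt must be positive")
  structure(list(p = p, nMax = nMax, nSeed = nSeed, dt = dt, tEnd = tEnd,
                 founder = founder, sampleSize = as.integer(sampleSize),
                 sampleTimes = sampleTimes, seed = as.integer(seed)),
            class = "simConfig")
}

# string -> integer-vector parse cache shared across simulation steps, with
# cached per-karyotype totals and truncated-binomial missegregation weights
makeParseCache <- function() {
  cache <- new.env(parent = emptyenv())
  pmCache <- new.env(parent = emptyenv())
  cCache <- new.env(parent = emptyenv())
  list(
    getC = function(keys) {     # total copy number per karyotype string
      vals <- mget(keys, envir = cCache, ifnotfound = list(NULL))
      missIdx <- vapply(vals, is.null, logical(1L))
      for (key in keys[missIdx]) {
        v <- cache[[key]]
        if (is.null(v)) {
          v <- parseKaryotype(key)
          cache[[key]] <- v
        }
        cCache[[key]] <- sum(v)
      }
      if (any(missIdx))
        vals[missIdx] <- mget(keys[missIdx], envir = cCache)
      unlist(vals, use.names = FALSE)
    },
    get = function(key) {
      v <- cache[[key]]
      if (is.null(v)) {
        v <- parseKaryotype(key)
        cache[[key]] <- v
      }
      v
    },
    put = function(key, v) cache[[key]] <- v,
    # P(m copies missegregate | m >= 1) weights for a cell with C copies
    pm = function(C, p) {
      key <- as.character(C)
      v <- pmCache[[key]]
      if (is.null(v)) {
        v <- stats::dbinom(seq_len(C), C, p)
        pmCache[[key]] <- v
      }
      v
    })
}

# Resolve fitness for karyotype strings with caching; kills (NA) nonviable.
makeFitnessCache <- function(landscape) {
  cache <- new.env(parent = emptyenv())
  function(keys) {
    vals <- mget(keys, envir = cache, ifnotfound = list(NULL))
    missIdx <- vapply(vals, is.null, logical(1L))
    if (any(missIdx)) {
      miss <- keys[missIdx]
      f <- fitnessOf(landscape, miss)
      for (i in seq_along(miss)) cache[[miss[i]]] <- f[i]
      vals[missIdx] <- as.list(f)
    }
    unlist(vals, use.names = FALSE)
  }
}

#' Advance the population by one time step
#'
#' One binomial-thinning update: divisions (or deaths, for negative fitness)
#' are drawn per karyotype, missegregating divisions are resolved cell by
#' cell through the per-copy kernel, and nonviable daughters (zero-copy
#' chromosome, or outside a lethal-policy LUT) are removed.
#'
#' @param state list with `counts` (named integer vector, names = karyotype
#'   strings) and `t` (days).
#' @param landscape a landscape object or function accepted by
#'   [fitnessOf()].
#' @param p per-copy missegregation probability.
#' @param dt time step in days.
#' @param fitnessFun,parseCache optional pre-built caches (internal use).
#' @return Updated state.
#' @export
stepPopulation <- function(state, landscape, p, dt,
                           fitnessFun = NULL, parseCache = NULL) {
  counts <- state$counts
  counts <- counts[counts > 0]
  if (!length(counts)) return(list(counts = counts, t = state$t + dt))
  if (is.null(fitnessFun)) fitnessFun <- makeFitnessCache(landscape)
  f <- fitnessFun(names(counts))
  dead <- is.na(f)
  if (any(dead)) {           # lethal out-of-table karyotypes
    counts <- counts[!dead]
    f <- f[!dead]
    if (!length(counts)) return(list(counts = counts, t = state$t + dt))
  }
  if (any(abs(f) * dt >= 1))
    stop("|fitness| * dt >= 1 for karyotype ",
         names(counts)[which.max(abs(f))], "; use a smaller dt")
  grow <- f >= 0
  ndiv <- integer(length(counts))
  ndiv[grow] <- rbinom(sum(grow), counts[grow], f[grow] * dt)
  ndeath <- integer(length(counts))
  ndeath[!grow] <- rbinom(sum(!grow), counts[!grow], -f[!grow] * dt)
  counts <- counts - ndeath

  if (any(ndiv > 0)) {
    if (p == 0) {
      counts <- counts + ndiv          # clean divisions only
    } else {
      if (is.null(parseCache)) parseCache <- makeParseCache()
      idx <- which(ndiv > 0)
      C <- parseCache$getC(names(counts)[idx])
      nms <- rbinom(length(idx), ndiv[idx], 1 - (1 - p)^C)
      # clean divisions: +1 cell; missegregating: parent replaced by the
      # daughters collected below
      counts[idx] <- counts[idx] + ndiv[idx] - 2L * nms
      tot <- sum(nms)
      if (tot > 0) {
        keys <- character(2L * tot)
        nk <- 0L
        for (ii in which(nms > 0)) {
          k <- parseCache$get(names(counts)[idx[ii]])
          pm <- parseCache$pm(C[ii], p)
          for (r in seq_len(nms[ii])) {
            dd <- drawMissegDaughters(k, p, pm)
            for (d in dd) {
              if (any(d == 0L)) next             # nonviable daughter
              key <- formatKaryotype(d)
              nk <- nk + 1L
              keys[nk] <- key
              parseCache$put(key, d)
            }
          }
        }
        if (nk > 0L) {
          tb <- table(keys[seq_len(nk)])
          hit <- match(names(tb), names(counts))
          old <- !is.na(hit)
          counts[hit[old]] <- counts[hit[old]] + as.integer(tb[old])
          if (any(!old))
            counts <- c(counts, setNames(as.integer(tb[!old]),
                                         names(tb)[!old]))
        }
      }
    }
  }
  counts <- counts[counts > 0]
  list(counts = counts, t = state$t + dt)
}

#' Run an agent-based simulation with serial passaging
#'
#' Iterates [stepPopulation()] from the founder population, passaging
#' (multinomial down-sampling to `nSeed` cells) whenever the population
#' reaches `nMax`, and recording a `sampleSize`-cell sample at every passage
#' event and at any requested `sampleTimes`.
#'
#' @param landscape landscape object or fitness function.
#' @param config a [simConfig()].
#' @return A `karyoSim` list: `samples` (data.frame time_days, karyotype,
#'   count over all observations), `passageTimes`, `finalState`, `extinct`
#'   flag, and the `config`.
#' @export
runSimulation <- function(landscape, config) {
  stopifnot(inherits(config, "simConfig"))
  founder <- if (is.character(config$founder) &&
                 is.null(names(config$founder))) {
    setNames(as.integer(config$nSeed), config$founder)
  } else {
    setNames(as.integer(config$founder), names(config$founder))
  }
  founderK <- karyoMatrix(names(founder))
  fitnessFun <- function(km) as.numeric(fitnessOf(landscape, km))
  out <- withSeed(config$seed,
    .abm_run(founderK, as.numeric(founder), fitnessFun, config$p,
             config$nMax, config$nSeed, config$dt, config$tEnd,
             config$sampleSize, as.numeric(sort(config$sampleTimes))))
  keys <- formatKaryotype(out$karyotypes)
  samples <- data.frame(time_days = out$sample_time,
                        karyotype = keys[out$sample_idx],
                        count = as.integer(out$sample_count))
  fin <- setNames(as.integer(out$finalCounts), keys)
  fin <- fin[fin > 0]
  structure(list(samples = samples, passageTimes = out$passageTimes,
                 finalState = list(counts = fin, t = out$t),
                 extinct = out$extinct, config = config),
            class = "karyoSim")
}

#' Multinomially sample cells from a population state
#'
#' Emulates single-cell sequencing of `n` cells drawn with replacement from
#' the current population frequencies (a multinomial sample).
#'
#' @param state population state (list with `counts`).
#' @param n number of cells to sample.
#' @param seed optional RNG seed for standalone use.
#' @return Named integer vector of sampled counts (zero entries dropped).
#' @export
sampleCounts <- function(state, n, seed = NULL) {
  if (n <= 0) stop("sample size must be positive")
  if (!sum(state$counts)) stop("cannot sample from an empty population")
  draw <- function() {
    s <- rmultinom(1L, n, state$counts)[, 1L]
    s[s > 0]
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Assemble sampled passages into a KaryoCounts object
#'
#' @param sim a `karyoSim` from [runSimulation()].
#' @param times which observation times to keep (default: all).
#' @return A [KaryoCounts-class] object.
#' @export
asKaryoCounts <- function(sim, times = NULL) {
  df <- sim$samples
  if (!nrow(df)) stop("simulation recorded no samples")
  if (!is.null(times)) df <- df[df$time_days %in% times, , drop = FALSE]
  ts <- sort(unique(df$time_days))
  ks <- unique(df$karyotype)
  m <- matrix(0L, length(ks), length(ts), dimnames = list(ks, NULL))
  m[cbind(match(df$karyotype, ks), match(df$time_days, ts))] <-
    as.integer(df$count)
  KaryoCounts(m, ts)
}

#' @export
print.karyoSim <- function(x, ...) {
  cat("karyoSim:", length(x$passageTimes), "passages over",
      x$config$tEnd, "days;",
      if (x$extinct) "population went extinct" else
        paste(sum(x$finalState$counts), "cells at end"), "\n")
  invisible(x)
}
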