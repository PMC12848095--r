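#' One-missegregation-step fitness-effect profile
#'
#' The 44 fitness changes `delta_f = f(neighbor) - f(k)` obtained by losing
#' or gaining one copy of each autosome, in fixed order (loss chr1, gain
#' chr1, ..., loss chr22, gain chr22). Losses into zero-copy states are
#' nonviable and returned as `NA`; neighbors outside the landscape's
#' look-up table are likewise `NA` and flagged.
#'
#' @param k karyotype string or vector; must be inside the landscape.
#' @param landscape anything accepted by [fitnessOf()].
#' @return An object of class `deltaFProfile`: list with `karyotype`,
#'   `effects` (named length-44 numeric), `viable` (logical, FALSE where the
#'   move leads to a zero-copy state), `missing` (logical, TRUE where the
#'   neighbor had no fitness value).
#' @export
deltaFProfile <- function(k, landscape) {
  if (!is.character(k)) k <- formatKaryotype(k)
  f0 <- fitnessOf(landscape, k)
  if (is.na(f0)) stop("karyotype ", k, " is not covered by the landscape")
  kv <- parseKaryotype(k)
  nb <- oneStepNeighbors(kv, allowZero = TRUE)
  chrom <- attr(nb, "chrom"); dir <- attr(nb, "direction")
  viable <- rowSums(nb == 0L) == 0L
  eff <- rep(NA_real_, 2L * N_AUTOSOMES)
  names(eff) <- paste0(rep(c("loss_chr", "gain_chr"), N_AUTOSOMES),
                       rep(seq_len(N_AUTOSOMES), each = 2L))
  fn <- rep(NA_real_, nrow(nb))
  fn[viable] <- fitnessOf(landscape, rownames(nb)[viable]) - f0
  pos <- 2L * (chrom - 1L) + ifelse(dir < 0, 1L, 2L)
  eff[pos] <- fn
  structure(list(karyotype = k, effects = eff,
                 viable = replace(rep(TRUE, 44L), pos[!viable], FALSE),
                 missing = is.na(eff) &
                   replace(rep(TRUE, 44L), pos[!viable], FALSE)),
            class = "deltaFProfile")
}

#' @export
print.deltaFProfile <- function(x, ...) {
  cat("deltaFProfile for", x$karyotype, "\n")
  cat("  ", sum(!is.na(x$effects)), "of 44 effects available; range [",
      signif(min(x$effects, na.rm = TRUE), 3), ",",
      signif(max(x$effects, na.rm = TRUE), 3), "] per day\n")
  invisible(x)
}

#' Correlation between two fitness-effect profiles
#'
#' Pearson correlation over the jointly viable, jointly available entries of
#' two delta-f profiles, with its Fisher z-transform `atanh(r)` for use in
#' downstream linear models.
#'
#' @param p1,p2 `deltaFProfile` objects.
#' @return List `r`, `z`, `n` (entries used). Zero variance in either
#'   profile yields `NaN` with a warning.
#' @export
profileCorrelation <- function(p1, p2) {
  ok <- !is.na(p1$effects) & !is.na(p2$effects)
  if (sum(ok) < 3L) stop("fewer than 3 jointly available effect entries")
  a <- p1$effects[ok]; b <- p2$effects[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(list(r = NaN, z = NaN, n = sum(ok)))
  }
  r <- cor(a, b)
  list(r = r, z = atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)), n = sum(ok))
}

#' Classify whole-genome-doubling status
#'
#' A karyotype is WGD+ when its modal chromosome copy number is at least 3;
#' modal ties are broken toward the smaller copy number (consistent with the
#' binned copy-number collapse rule).
#'
#' @param k karyotype string, vector, or matrix (one per row).
#' @return Character vector of "WGD+" / "WGD-".
#' @export
wgdClassify <- function(k) {
  if (is.character(k)) k <- karyoMatrix(k)
  if (!is.matrix(k)) k <- matrix(k, nrow = 1L)
  apply(k, 1L, function(v) {
    tb <- table(v)
    vals <- as.integer(names(tb))
    modal <- min(vals[tb == max(tb)])
    if (modal >= 3L) "WGD+" else "WGD-"
  })
}

#' Permutation Kolmogorov-Smirnov test on per-fit mean fitness effects
#'
#' Compares the distributions of per-landscape-fit mean fitness effects
#' between two groups (e.g. WGD+ vs WGD- fits). Averaging within each fit
#' before comparison avoids pseudo-replication; significance is assessed by
#' permuting the group labels among fits.
#'
#' @param values numeric vector, one mean effect per landscape fit.
#' @param labels two-level factor/character, one label per fit.
#' @param nPerm number of label permutations.
#' @param seed RNG seed.
#' @return List: `statistic` (KS D), `p_value`
#'   (`(1 + #perm >= obs) / (nPerm + 1)`), `nPerm`.
#' @export
permutationKSTest <- function(values, labels, nPerm = 10000L, seed = 1L) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly two levels")
  if (min(table(labels)) < 2L) stop("need at least 2 fits per label")
  # exact two-sample KS D via the sorted cumulative-step form; evaluate
  # only where the pooled sorted values change (correct under ties)
  ksD <- function(a, b) {
    comb <- c(a, b)
    ord <- order(comb)
    step <- rep(c(1 / length(a), -1 / length(b)),
                c(length(a), length(b)))[ord]
    cs <- cumsum(step)
    sorted <- comb[ord]
    n <- length(sorted)
    valid <- c(sorted[-1L] != sorted[-n], TRUE)
    max(abs(cs[valid]))
  }
  obs <- ksD(values[labels == lv[1L]], values[labels == lv[2L]])
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    sh <- sample(labels)
    ksD(values[sh == lv[1L]], values[sh == lv[2L]])
  }, numeric(1L)))
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (nPerm + 1),
       nPerm = nPerm)
}

#' Neighborhood and fitness features for novel-karyotype emergence
#'
#' For every candidate karyotype in the fitted set Theta that is absent from
#' the current sample zeta, computes the fractions `d1..d5` of the zeta
#' population lying exactly 1..5 missegregations (Manhattan steps) away,
#' plus the landscape fitness estimate, and labels whether the candidate is
#' present in the future sample Psi. By default fractions are cell-weighted
#' (weighted by zeta frequencies); `cloneWeighted = TRUE` counts each
#' distinct karyotype in zeta once.
#'
#' @param theta named numeric vector: fitness for every karyotype in Theta.
#' @param zeta named frequency vector of the current sample (support must be
#'   a subset of Theta).
#' @param psi character vector: karyotypes present in the future sample.
#' @param cloneWeighted weight each zeta clone equally instead of by
#'   abundance.
#' @return data.frame: karyotype, f, d1..d5, emerged (logical). Empty if
#'   Theta has no candidate outside zeta.
#' @export
emergenceFeatures <- function(theta, zeta, psi, cloneWeighted = FALSE) {
  if (!all(names(zeta) %in% names(theta)))
    stop("zeta must be a subset of theta")
  zeta <- zeta / sum(zeta)
  cand <- setdiff(names(theta), names(zeta))
  if (!length(cand))
    return(data.frame(karyotype = character(0), f = numeric(0),
                      d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
                      d4 = numeric(0), d5 = numeric(0),
                      emerged = logical(0)))
  zm <- karyoMatrix(names(zeta))
  w <- if (cloneWeighted) rep(1 / nrow(zm), nrow(zm)) else as.numeric(zeta)
  feats <- t(vapply(cand, function(s) {
    d <- manhattanDist(zm, parseKaryotype(s))
    vapply(1:5, function(i) sum(w[d == i]), numeric(1L))
  }, numeric(5L)))
  out <- data.frame(karyotype = cand, f = unname(theta[cand]), feats,
                    emerged = cand %in% psi, row.names = NULL)
  colnames(out)[3:7] <- paste0("d", 1:5)
  out
}

#' Logistic model of novel karyotype emergence
#'
#' Maximum-likelihood binomial logistic regression of emergence on fitness
#' and the neighborhood fractions:
#' `logit P(emerged) = b0 + bf * f + sum_i bi * di`, with two-sided Wald
#' z-tests per coefficient. Perfect separation is detected and flagged
#' rather than silently returning divergent coefficients.
#'
#' @param features data.frame from [emergenceFeatures()].
#' @return List: `coefficients`, `z`, `p_values`, `separation` flag,
#'   `model` (the `glm` fit).
#' @export
fitEmergenceModel <- function(features) {
  if (length(unique(features$emerged)) < 2L)
    stop("both emerged and non-emerged candidates are required")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(emerged ~ f + d1 + d2 + d3 + d4 + d5,
               family = stats::binomial(), data = features),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 50, na.rm = TRUE)) sep <- TRUE
  if (sep) warning("possible perfect separation: coefficients unreliable")
  sm <- summary(fit)$coefficients
  list(coefficients = sm[, "Estimate"], z = sm[, "z value"],
       p_values = sm[, "Pr(>|z|)"], separation = sep, model = fit)
}

#' Randomly select non-overlapping passage trajectories from a lineage graph
#'
#' Repeatedly starts at a random root (in-degree zero node of the remaining
#' graph) and follows random out-edges to a terminal node, removing the
#' visited passages; repeats until no path of at least `minLength` passages
#' remains. The returned trajectories are pairwise node-disjoint, so
#' replicates built from them share no passage data.
#'
#' @param graph an [igraph::graph] (directed, acyclic) or a two-column
#'   edge data.frame (from, to).
#' @param seed RNG seed (varying it varies the selected set).
#' @param minLength minimum passages per trajectory.
#' @return List of character vectors of passage node names.
#' @export
sampleNonoverlappingTrajectories <- function(graph, seed = 1L,
                                             minLength = 2L) {
  if (is.data.frame(graph))
    graph <- igraph::graph_from_data_frame(graph, directed = TRUE)
  if (!igraph::is_dag(graph)) stop("lineage graph must be acyclic")
  withSeed(seed, {
    g <- graph
    out <- list()
    repeat {
      if (igraph::vcount(g) == 0L) break
      roots <- igraph::V(g)[igraph::degree(g, mode = "in") == 0L]
      if (!length(roots)) break
      v <- roots[[sample.int(length(roots), 1L)]]
      path <- igraph::V(g)$name[as.integer(v)]
      repeat {
        nxt <- igraph::neighbors(g, v, mode = "out")
        if (!length(nxt)) break
        v <- nxt[[sample.int(length(nxt), 1L)]]
        path <- c(path, igraph::V(g)$name[as.integer(v)])
      }
      if (length(path) >= minLength) out[[length(out) + 1L]] <- path
      g <- igraph::delete_vertices(g, path)
    }
    out
  })
}

#' Growth-weighted missegregation transition matrix over a charted region
#'
#' Approximate one-generation transfer operator restricted to the charted
#' states: `A[i, j] = Pr(i | j; p) * exp(f_j * dt)`, the per-division
#' missegregation kernel times the parent's growth weight. Flux to states
#' outside the region is discarded and the *mutation kernel* columns are
#' renormalized to 1 over the region (the truncation is the "approximate"
#' part); the growth factor is deliberately left unnormalized -- a
#' column-stochastic renormalization after growth weighting would cancel
#' `exp(f_j dt)` exactly and erase selection from the operator. The steady
#' state is therefore the Perron (leading) eigenvector of a nonnegative,
#' generally non-stochastic matrix. Transitions are enumerated up to
#' Manhattan distance `maxDist` (multi-chromosome events beyond that carry
#' negligible probability at plausible rates).
#'
#' @param landscape [FittedLandscape-class], [LUTLandscape-class], or a
#'   named fitness vector over the region.
#' @param p missegregation probability per copy per division.
#' @param dt generation step (days) for the growth weight.
#' @param maxDist transition enumeration cutoff (Manhattan steps).
#' @return Nonnegative sparse matrix (dgCMatrix) over the region; each
#'   column sums to the parent's growth weight `exp(f_j * dt)`.
#' @export
buildTransitionMatrix <- function(landscape, p, dt = 1, maxDist = 2L) {
  tab <- if (methods::is(landscape, "FittedLandscape"))
    setNames(landscape@lut$mean_fitness, landscape@lut$karyotype)
  else if (methods::is(landscape, "LUTLandscape")) landscape@table
  else landscape
  states <- names(tab)
  N <- length(states)
  if (N > 4000L)
    stop("transition matrix enumeration is quadratic; region too large (",
         N, " states)")
  km <- karyoMatrix(states)
  D <- matrix(0L, N, N)
  for (c in seq_len(N_AUTOSOMES))
    D <- D + abs(outer(km[, c], km[, c], "-"))
  idx <- which(D <= maxDist, arr.ind = TRUE)   # (child i, parent j)
  pr <- numeric(nrow(idx))
  for (j in seq_len(N)) {
    rows <- idx[, 2L] == j
    if (!any(rows)) next
    pr[rows] <- transitionProbMany(km[j, ], km[idx[rows, 1L], , drop = FALSE],
                                   p)
  }
  A <- Matrix::sparseMatrix(i = idx[, 1L], j = idx[, 2L], x = pr,
                            dims = c(N, N))
  cs <- Matrix::colSums(A)
  if (any(cs == 0)) stop("a column has no within-region transition mass")
  A <- A %*% Matrix::Diagonal(N, exp(tab * dt) / cs)
  dimnames(A) <- list(states, states)
  A
}


#' Steady-state distribution of a nonnegative transition operator
#'
#' Perron (leading) eigenvector, normalized to sum 1: power iteration for
#' large systems, repeated matrix squaring for small ones (robust to the
#' tiny spectral gaps that arise at very low missegregation rates).
#'
#' @param A nonnegative square matrix (dense or sparse), e.g. from
#'   [buildTransitionMatrix()].
#' @param tol convergence tolerance on the max absolute change.
#' @param maxIter iteration cap.
#' @return Named frequency vector. Reducible chains (e.g. identity-like
#'   matrices) converge to a stationary vector that depends on the uniform
#'   initialization and are flagged with a warning.
#' @export
steadyState <- function(A, tol = 1e-10, maxIter = 100000L) {
  n <- nrow(A)
  flagReducible <- function(x) {
    # a column with all mass on the diagonal is absorbing: the limit then
    # depends on the (uniform) initialization
    offdiag <- Matrix::colSums(A) - Matrix::diag(A)
    if (any(offdiag <= 1e-15 * Matrix::colSums(A)))
      warning("matrix has absorbing/reducible structure; steady state ",
              "depends on initialization")
    setNames(x, rownames(A))
  }
  if (n <= 600L) {
    # repeated squaring handles the tiny spectral gaps of low mutation
    # rates, where plain power iteration mixes in O(1/p) steps
    M <- as.matrix(A)
    M <- M / max(M)
    xOld <- rep(NA_real_, n)
    for (sq in seq_len(80L)) {
      M <- M %*% M
      M <- M / max(M)                 # scale only: keep the Perron direction
      x <- rowSums(M)
      x <- x / sum(x)
      if (!anyNA(xOld) && max(abs(x - xOld)) < tol)
        return(flagReducible(x))
      xOld <- x
    }
    stop("steady state did not converge by repeated squaring")
  }
  x <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    x2 <- as.numeric(A %*% x)
    x2 <- x2 / sum(x2)
    if (max(abs(x2 - x)) < tol) return(flagReducible(x2))
    x <- x2
  }
  stop("power iteration did not converge within ", maxIter, " iterations")
}

#' Screen steady-state karyotype dominance across missegregation rates
#'
#' For each rate, builds the growth-weighted transition matrix, finds its
#' steady state, and reports the dominant (most frequent) karyotype and its
#' Manhattan distance to the dominant karyotype at the lowest screened rate.
#' A positive distance at higher rates is the error-threshold signature: the
#' population abandons a narrow fitness peak for a broader, mutationally
#' robust region.
#'
#' @param landscape as in [buildTransitionMatrix()].
#' @param rates missegregation rates to screen (>= 2).
#' @param dt generation step (days).
#' @param maxDist transition enumeration cutoff.
#' @return List: `summary` data.frame (rate, dominant, distance),
#'   `steadyStates` matrix (states x rates).
#' @export
dominanceScreen <- function(landscape, rates, dt = 1, maxDist = 2L) {
  stopifnot(length(rates) >= 2L)
  rates <- sort(rates)
  tab <- if (methods::is(landscape, "FittedLandscape"))
    setNames(landscape@lut$mean_fitness, landscape@lut$karyotype)
  else if (methods::is(landscape, "LUTLandscape")) landscape@table
  else landscape
  states <- names(tab)
  sss <- vapply(rates, function(r)
    steadyState(buildTransitionMatrix(tab, r, dt, maxDist)),
    numeric(length(states)))
  rownames(sss) <- states
  dom <- states[apply(sss, 2L, which.max)]
  ref <- parseKaryotype(dom[1L])
  dist <- vapply(dom, function(s) manhattanDist(parseKaryotype(s), ref),
                 integer(1L))
  list(summary = data.frame(rate = rates, dominant = dom,
                            distance = as.integer(dist), row.names = NULL),
       steadyStates = sss)
}

#' Assign karyotypes to missegregation-rate response groups
#'
#' Among the `topN` karyotypes most abundant anywhere across the screened
#' rates, correlates steady-state frequency with rate: negative correlation
#' puts a karyotype in group "x" (dominant at low rates), positive in group
#' "y" (dominant at high rates); weak correlations stay unassigned.
#'
#' @param steadyStates states x rates frequency matrix (rownames = states).
#' @param rates the screened rates (>= 3).
#' @param topN number of most-abundant karyotypes considered.
#' @param threshold minimum |Pearson r| for assignment.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame: karyotype, r, group ("x", "y" or NA).
#' @export
assignRateResponseGroups <- function(steadyStates, rates, topN = 400L,
                                     threshold = 0.2,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(rates) >= 3L, ncol(steadyStates) == length(rates))
  keep <- order(apply(steadyStates, 1L, max), decreasing = TRUE)
  keep <- keep[seq_len(min(topN, length(keep)))]
  r <- apply(steadyStates[keep, , drop = FALSE], 1L, function(v)
    if (sd(v) == 0) NA_real_ else cor(v, rates, method = method))
  group <- ifelse(is.na(r) | abs(r) < threshold, NA_character_,
                  ifelse(r < 0, "x", "y"))
  data.frame(karyotype = rownames(steadyStates)[keep], r = as.numeric(r),
             group = group, row.names = NULL)
}
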