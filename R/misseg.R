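#' Per-chromosome daughter copy-number kernel
#'
#' During one division each of the `n` copies of a chromosome missegregates
#' independently with probability `p`; a missegregating copy sends both
#' sister chromatids to the same daughter cell, chosen uniformly. If `m`
#' copies missegregate (`m ~ Binomial(n, p)`) and `g` of them resolve toward
#' the focal daughter (`g ~ Binomial(m, 1/2)`), that daughter inherits
#' `n + 2g - m` copies. The distribution is symmetric about `n` and supported
#' on `0..2n`.
#'
#' @param n parent copy number (non-negative integer).
#' @param p per-copy missegregation probability per division, in [0, 0.5].
#' @return Numeric vector of length `2n + 1`; element `d + 1` is
#'   `P(daughter copy number = d)`. Sums to 1.
#' @examples
#' daughterKernel(2, 0.1)
#' @export
daughterKernel <- function(n, p) {
  stopifnot(n >= 0L, n == round(n))
  if (p < 0 || p > 0.5) stop("missegregation probability p must be in [0, 0.5]")
  if (n == 0L) return(1)  # no copies, nothing to missegregate
  d <- 0:(2L * n)
  pr <- vapply(d, function(dd) {
    m <- 0:n
    g2 <- dd - n + m          # 2g for each m
    ok <- g2 >= 0 & g2 <= 2 * m & g2 %% 2 == 0
    sum(stats::dbinom(m[ok], n, p) * stats::dbinom(g2[ok] / 2, m[ok], 0.5))
  }, numeric(1L))
  pr
}

#' Transition probability between whole karyotypes in one division
#'
#' Probability that a daughter of a cell with karyotype `parent` has
#' karyotype `child`, under independent per-copy missegregation at rate `p`
#' on each of the 22 chromosomes: the product over chromosomes of
#' [daughterKernel()] evaluated at the child's copy numbers. No viability
#' truncation is applied here; zero-copy daughters are handled by the caller
#' (the simulator kills them, inference excludes them).
#'
#' @param parent,child karyotype vectors or strings.
#' @param p per-copy missegregation probability.
#' @return Probability in [0, 1]. For `p = 0` this is 1 iff
#'   `child == parent`.
#' @export
transitionProb <- function(parent, child, p) {
  if (is.character(parent)) parent <- parseKaryotype(parent)
  if (is.character(child)) child <- parseKaryotype(child)
  stopifnot(length(parent) == N_AUTOSOMES, length(child) == N_AUTOSOMES)
  pr <- 1
  for (c in seq_len(N_AUTOSOMES)) {
    n <- parent[c]
    d <- child[c]
    if (d < 0L || d > 2L * n) return(0)
    pr <- pr * daughterKernel(n, p)[d + 1L]
    if (pr == 0) return(0)
  }
  pr
}

#' Vectorized transition probabilities parent -> many children
#'
#' @param parent karyotype vector or string.
#' @param children integer matrix (rows = child karyotypes).
#' @param p per-copy missegregation probability.
#' @return Numeric vector of probabilities, one per row of `children`.
#' @keywords internal
transitionProbMany <- function(parent, children, p) {
  if (is.character(parent)) parent <- parseKaryotype(parent)
  if (is.character(children)) children <- karyoMatrix(children)
  kernels <- lapply(unique(parent), function(n) daughterKernel(n, p))
  names(kernels) <- as.character(unique(parent))
  pr <- rep(1, nrow(children))
  for (c in seq_len(N_AUTOSOMES)) {
    kern <- kernels[[as.character(parent[c])]]
    d <- children[, c]
    v <- numeric(length(d))
    ok <- d >= 0L & d <= 2L * parent[c]
    v[ok] <- kern[d[ok] + 1L]
    pr <- pr * v
  }
  pr
}

# Draw the two daughter karyotypes of a dividing cell, conditioned on at
# least one copy missegregating. totalCopies = sum(k). Used by the ABM: the
# (common) no-missegregation case is handled in bulk by the caller.
drawMissegDaughters <- function(k, p, pm = NULL) {
  C <- sum(k)
  # m_total ~ Binomial(C, p) truncated to >= 1, via inverse CDF
  if (is.null(pm)) pm <- stats::dbinom(1:C, C, p)
  mTotal <- sample.int(C, 1L, prob = pm)
  # allocate the missegregating copies uniformly among physical copies
  copyChrom <- rep.int(seq_len(N_AUTOSOMES), k)
  hit <- if (C == 1L) copyChrom else copyChrom[sample.int(C, mTotal)]
  m <- tabulate(hit, nbins = N_AUTOSOMES)
  g <- stats::rbinom(N_AUTOSOMES, m, 0.5)
  delta <- 2L * g - m
  list(k + delta, k - delta)
}
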