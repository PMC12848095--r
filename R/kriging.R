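# Matern nu = 3/2 covariance on Euclidean distance matrix D
maternCov <- function(D, ell, sigma2) {
  a <- sqrt(3) * D / ell
  sigma2 * (1 + a) * exp(-a)
}

euclidDist <- function(A, B = NULL) {
  if (is.null(B)) B <- A
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit a Matern-3/2 Gaussian process (Kriging) to fitness anchors
#'
#' Ordinary Kriging over raw 22-D copy-number vectors with Euclidean
#' distance, a single isotropic length-scale and a constant (GLS-estimated)
#' mean. Length-scale and process variance are chosen by maximizing the
#' marginal likelihood; the nugget (observation-noise variance) is fixed
#' from the configuration. With `nugget = 0` the predictor interpolates the
#' anchors exactly.
#'
#' @param X anchor karyotypes: integer matrix (rows) or character vector.
#' @param y anchor fitness values (per day).
#' @param nugget observation-noise variance added to the diagonal.
#' @param ellRange optional length-scale search bounds.
#' @param maxHyperN anchors beyond this count are deterministically
#'   subsampled (every k-th) for the marginal-likelihood hyperparameter
#'   search only; the final interpolation weights always use all anchors.
#' @return A `krigingModel` list (frozen; use [predictKriging()]).
#' @export
fitKriging <- function(X, y, nugget = 1e-4, ellRange = NULL,
                       maxHyperN = 200L) {
  if (is.character(X)) X <- karyoMatrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 3L) stop("need at least 3 anchors")
  if (sd(y) == 0) stop("degenerate anchors: zero fitness variance")
  sub <- if (nrow(X) > maxHyperN)
    seq(1L, nrow(X), length.out = maxHyperN) else seq_len(nrow(X))
  Xh <- X[sub, , drop = FALSE]; yh <- y[sub]
  D <- euclidDist(Xh)
  med <- median(D[upper.tri(D)])
  if (med == 0) med <- 1
  if (is.null(ellRange)) ellRange <- c(med / 20, med * 20)
  jitter <- 1e-10 * max(1, var(y))

  nll <- function(par) {
    ell <- exp(par[1L]); sigma2 <- exp(par[2L])
    K <- maternCov(D, ell, sigma2)
    diag(K) <- diag(K) + nugget + jitter
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    ones <- rep(1, length(yh))
    Ki1 <- backsolve(L, forwardsolve(t(L), ones))
    beta <- sum(Ki1 * yh) / sum(Ki1 * ones)
    r <- yh - beta
    Kir <- backsolve(L, forwardsolve(t(L), r))
    0.5 * sum(r * Kir) + sum(log(diag(L)))
  }
  init <- c(log(med), log(max(var(y), 1e-8)))
  opt <- optim(init, nll, method = "L-BFGS-B",
               lower = c(log(ellRange[1L]), log(1e-10)),
               upper = c(log(ellRange[2L]), log(1e4)),
               control = list(maxit = 30L))
  ell <- exp(opt$par[1L]); sigma2 <- exp(opt$par[2L])
  D <- euclidDist(X)

  K <- maternCov(D, ell, sigma2)
  diag(K) <- diag(K) + nugget + jitter
  L <- chol(K)
  ones <- rep(1, length(y))
  Ki1 <- backsolve(L, forwardsolve(t(L), ones))
  beta <- sum(Ki1 * y) / sum(Ki1 * ones)
  alpha <- backsolve(L, forwardsolve(t(L), y - beta))
  structure(list(X = X, y = y, ell = ell, sigma2 = sigma2, nugget = nugget,
                 jitter = jitter, beta = beta, alpha = alpha, L = L),
            class = "krigingModel")
}

#' Predict fitness at new karyotypes from a fitted Kriging model
#'
#' @param model a `krigingModel` from [fitKriging()].
#' @param Xnew karyotype matrix or character vector.
#' @param computeSd also return predictive standard deviations (requires a
#'   triangular solve per point; skip for large look-up tables when only
#'   means are needed).
#' @return List with `mean` and `sd` vectors (`sd` is `NA` when skipped).
#' @export
predictKriging <- function(model, Xnew, computeSd = TRUE) {
  if (is.character(Xnew)) Xnew <- karyoMatrix(Xnew)
  if (!is.matrix(Xnew)) Xnew <- matrix(Xnew, nrow = 1L)
  n <- nrow(Xnew)
  mu <- numeric(n)
  s2 <- rep(NA_real_, n)
  Lt <- t(model$L)
  for (start in seq(1L, n, by = 4000L)) {   # chunked: bounds memory
    ix <- start:min(start + 3999L, n)
    Ks <- maternCov(euclidDist(Xnew[ix, , drop = FALSE], model$X),
                    model$ell, model$sigma2)
    mu[ix] <- model$beta + as.numeric(Ks %*% model$alpha)
    if (computeSd) {
      V <- forwardsolve(Lt, t(Ks))
      s2[ix] <- pmax(model$sigma2 - colSums(V^2), 0)
    }
  }
  list(mean = mu, sd = sqrt(s2))
}

#' @export
print.krigingModel <- function(x, ...) {
  cat("krigingModel (Matern nu=3/2):", nrow(x$X), "anchors; length-scale",
      signif(x$ell, 4), "; sigma2", signif(x$sigma2, 4), "; nugget",
      x$nugget, "\n")
  invisible(x)
}

#' Leave-one-out cross-validation score of a fitted landscape
#'
#' Each frequent-clone anchor is left out in turn and its fitness predicted
#' by Kriging refit on the remaining anchors (neighbor anchors always
#' retained); hyperparameters are held at the full-fit values, for which the
#' leave-one-out residuals have the exact closed form
#' `e_i = alpha_i / [K^-1]_ii`. The score is the predictive R-squared
#' `1 - sum e_i^2 / sum (y_i - ybar)^2` over the held-out frequent anchors:
#' at most 1, unbounded below, with values <= 0 indicating no better than
#' the mean predictor.
#'
#' @param X,y all anchors (karyotypes and fitness).
#' @param frequentIdx indices of the frequent-clone anchors (default: all).
#' @param nugget observation-noise variance.
#' @param model optional pre-fitted `krigingModel` on exactly (X, y).
#' @return Scalar CV score (NaN, with a warning, if the held-out anchor
#'   fitnesses have zero variance).
#' @export
cvScore <- function(X, y, frequentIdx = seq_along(y), nugget = 1e-4,
                    model = NULL) {
  if (length(frequentIdx) < 4L)
    stop("need at least 4 frequent anchors for cross-validation")
  if (is.null(model)) model <- fitKriging(X, y, nugget = nugget)
  yf <- y[frequentIdx]
  if (sd(yf) == 0) {
    warning("zero variance among held-out anchors; CV score undefined")
    return(NaN)
  }
  Kinv <- chol2inv(model$L)
  # closed-form LOO residual for the GLS-mean GP at fixed hyperparameters
  e <- model$alpha[frequentIdx] / diag(Kinv)[frequentIdx]
  1 - sum(e^2) / sum((yf - mean(yf))^2)
}
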