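# Exact solver for the balanced transportation problem
#   min sum_ij C_ij x_ij  s.t.  rowSums(x) = a, colSums(x) = b, x >= 0
# via the transportation simplex (src/transport.cpp): northwest-corner
# initial basis + MODI (u-v potential) pivoting with tree potentials;
# degeneracy broken by an infinitesimal deterministic supply perturbation.
transportPlan <- function(a, b, C) {
  stopifnot(nrow(C) == length(a), ncol(C) == length(b),
            all(a >= 0), all(b >= 0))
  .transport_simplex(as.numeric(a), as.numeric(b),
                     matrix(as.numeric(C), nrow(C)))
}

# reference R implementation of the same pivoting scheme (kept for
# cross-checking the compiled solver on small instances)
transportPlanR <- function(a, b, C) {
  m <- length(a); n <- length(b)
  stopifnot(nrow(C) == m, ncol(C) == n, all(a >= 0), all(b >= 0))
  if (abs(sum(a) - sum(b)) > 1e-9 * max(sum(a), sum(b)))
    stop("unbalanced transportation problem")
  sc <- sum(a)
  a <- a / sc; b <- b / sc
  eps <- 1e-11
  a <- a + eps * seq_len(m)
  b[n] <- b[n] + eps * m * (m + 1) / 2

  nb <- m + n - 1L
  bi <- integer(nb); bj <- integer(nb); xb <- numeric(nb)
  i <- 1L; j <- 1L; k <- 0L
  ra <- a; rb <- b
  while (k < nb) {
    k <- k + 1L
    bi[k] <- i; bj[k] <- j
    v <- min(ra[i], rb[j])
    xb[k] <- v
    ra[i] <- ra[i] - v; rb[j] <- rb[j] - v
    if (i < m && (ra[i] <= rb[j] || j == n)) i <- i + 1L else j <- j + 1L
  }

  maxIter <- 50L * (m + n)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    # adjacency of the basis tree over nodes 1..m (rows), m+1..m+n (cols)
    edgeNodeA <- bi
    edgeNodeB <- m + bj
    adj <- vector("list", m + n)
    byA <- split(seq_len(nb), edgeNodeA)
    byB <- split(seq_len(nb), edgeNodeB)
    adj[as.integer(names(byA))] <- byA
    for (nm in names(byB)) {
      ni <- as.integer(nm)
      adj[[ni]] <- c(adj[[ni]], byB[[nm]])
    }
    # potentials by BFS from row node 1 (u[1] = 0)
    u <- numeric(m); v <- numeric(n)
    pot <- rep(NA_real_, m + n); pot[1L] <- 0
    queue <- c(1L, integer(m + n - 1L)); qh <- 1L; qt <- 1L
    parentEdge <- integer(m + n)
    while (qh <= qt) {
      nd <- queue[qh]; qh <- qh + 1L
      for (e in adj[[nd]]) {
        other <- if (edgeNodeA[e] == nd) edgeNodeB[e] else edgeNodeA[e]
        if (is.na(pot[other])) {
          pot[other] <- C[bi[e], bj[e]] - pot[nd]
          parentEdge[other] <- e
          qt <- qt + 1L; queue[qt] <- other
        }
      }
    }
    u <- pot[seq_len(m)]; v <- pot[m + seq_len(n)]

    red <- C - outer(u, v, "+")
    ent <- arrayInd(which.min(red), dim(red))
    if (red[ent] >= -1e-12) { converged <- TRUE; break }   # optimal

    # unique tree path between the entering cell's endpoints
    from <- ent[1L]; to <- m + ent[2L]
    # walk both endpoints to the root via parentEdge, collect paths
    pathOf <- function(nd) {
      p <- integer(0)
      while (nd != 1L) {
        e <- parentEdge[nd]
        p <- c(p, e)
        nd <- if (edgeNodeA[e] == nd) edgeNodeB[e] else edgeNodeA[e]
      }
      p
    }
    pf <- pathOf(from); pt_ <- pathOf(to)
    common <- intersect(pf, pt_)
    path <- c(setdiff(pf, common), rev(setdiff(pt_, common)))
    # order path from 'from' to 'to'; signs alternate starting with -
    # (edges adjacent to the entering (+) cell take -)
    signs <- rep(c(-1, 1), length.out = length(path))
    minus <- path[signs < 0]
    theta <- min(xb[minus])
    leave <- minus[which.min(xb[minus])]
    xb[path] <- xb[path] + signs * theta
    bi[leave] <- ent[1L]; bj[leave] <- ent[2L]
    xb[leave] <- theta
  }
  if (!converged) stop("transportation simplex did not converge")
  cost <- sum(C[cbind(bi, bj)] * xb)
  list(cost = cost, basis = cbind(i = bi, j = bj), mass = xb,
       iterations = iter)
}

#' Exact Wasserstein-1 distance between karyotype distributions
#'
#' Exact discrete optimal-transport cost between two frequency
#' distributions over karyotypes, with Euclidean (default) or Manhattan
#' ground metric on the 22-D copy-number vectors. Solved by the
#' transportation simplex; symmetric, zero iff the distributions are equal.
#'
#' @param d1,d2 named numeric vectors: karyotype string -> relative
#'   frequency (each sums to 1; they are renormalized defensively).
#' @param ground ground metric on karyotype vectors.
#' @return Non-negative scalar distance (copy-number units).
#' @export
wassersteinDist <- function(d1, d2, ground = c("euclidean", "manhattan")) {
  ground <- match.arg(ground)
  d1 <- d1[d1 > 0] / sum(d1); d2 <- d2[d2 > 0] / sum(d2)
  k1 <- karyoMatrix(names(d1)); k2 <- karyoMatrix(names(d2))
  C <- if (ground == "euclidean") euclidDist(k1, k2) else {
    M <- matrix(0, nrow(k1), nrow(k2))
    for (i in seq_len(nrow(k1)))
      M[i, ] <- rowSums(abs(sweep(k2, 2L, k1[i, ])))
    M
  }
  transportPlan(as.numeric(d1), as.numeric(d2), C)$cost
}
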