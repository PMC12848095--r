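# shared helpers: small karyotype constructors and synthetic count tables

diploid <- function() rep(2L, N_AUTOSOMES)

kstr <- function(v) formatKaryotype(as.integer(v))

# diploid with one chromosome altered
kAlt <- function(chrom, copies) {
  v <- diploid()
  v[chrom] <- as.integer(copies)
  v
}

# exact replicator counts (no sampling noise) for clones S with fitness f
replicatorCounts <- function(S, f, x0, times, depth = 1e4) {
  xt <- replicatorSolution(f, x0, times)
  cnt <- round(t(xt) * depth)
  rownames(cnt) <- S
  KaryoCounts(cnt, times)
}

# multinomially sampled replicator counts
sampledReplicatorCounts <- function(S, f, x0, times, n) {
  xt <- replicatorSolution(f, x0, times)
  cnt <- vapply(seq_along(times), function(j)
    rmultinom(1L, n, xt[j, ])[, 1L], integer(length(S)))
  rownames(cnt) <- S
  KaryoCounts(cnt, times)
}

# brute-force Monte Carlo of per-copy missegregation for one chromosome:
# each of n copies missegregates w.p. p; a missegregating copy resolves to
# a uniformly chosen daughter (+1 there, -1 in the sister). Returns the
# empirical distribution of the focal daughter's copy number.
mcDaughterKernel <- function(n, p, nSim) {
  m <- rbinom(nSim, n, p)
  g <- rbinom(nSim, m, 0.5)
  d <- n + 2L * g - m
  tabulate(d + 1L, nbins = 2L * n + 1L) / nSim
}

# full-cell Monte Carlo oracle: simulate one division of `parent` under
# per-copy missegregation and count daughters matching `child`
mcTransitionProb <- function(parent, child, p, nSim) {
  C <- sum(parent)
  copyChrom <- rep.int(seq_along(parent), parent)
  hits <- 0L
  for (s in seq_len(nSim)) {
    mis <- runif(C) < p
    m <- tabulate(copyChrom[mis], nbins = length(parent))
    g <- rbinom(length(parent), m, 0.5)
    if (all(parent + 2L * g - m == child)) hits <- hits + 1L
  }
  hits / nSim
}
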