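---
title: "Charting local karyotype fitness landscapes from longitudinal single-cell data"
author: "karyofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting local karyotype fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chromosomally unstable cell populations explore karyotype space by
whole-chromosome missegregation: at each division, every chromosome copy
has a small probability *p* of missegregating, sending both sister
chromatids to one daughter and changing that chromosome's copy number by
±1 in each daughter. Which of the resulting aneuploid karyotypes expand
is decided by a fitness landscape *f*(**k**) mapping the 22-vector of
autosome copy numbers to a net growth rate (per day). The landscape
cannot be charted globally — at up to eight copies per chromosome there
are more than 10^19 states — but longitudinal single-cell sequencing of
serially passaged populations observes the small region a population
actually traverses, and that region carries enough signal to estimate
fitness locally.

`karyofit` implements the full loop: inference of a local landscape from
karyotype count time series, simulation of evolving populations on known
or fitted landscapes, forecasting, and downstream analyses of fitted
landscapes.

## Data model

Input data are passages: at observation times *t₁ < t₂ < …* (days), a
few hundred cells are sampled and each is reduced to a 22-element
integer karyotype (for binned copy-number calls,
`modalKaryotypeFromBins()` takes the modal integer per autosome, ties
resolved toward the smaller copy number — a deterministic rule that is
conservative for whole-genome-doubling classification). Counts live in a
`KaryoCounts` object, a `SummarizedExperiment` whose rows are karyotype
strings ("2.2.…2") and whose columns carry `time_days`.

## Inference

**Stage 1 — frequent clones.** Karyotypes with at least `minObs` total
observed cells form the frequent set S. Their frequencies follow the
replicator equation dxᵢ/dt = xᵢ(fᵢ − φ), φ = Σ xⱼfⱼ, with closed-form
solution xᵢ(t) ∝ xᵢ(0)·exp(fᵢt). A count-weighted least-squares fit of
log-frequency slopes (the exact solution of the corresponding convex
QP, with a +0.5 continuity correction for zero counts) initializes a
multinomial maximum-likelihood refinement with analytic gradients.
Initial frequencies are fixed at first-passage observed frequencies
(continuity-corrected only if some clone is absent there) rather than
estimated jointly: this keeps the parameter count at |S|−1, is exact on
noise-free data, and in simulations the extra variance from estimating
x(0) was never compensated by likelihood gains. Only fitness
*differences* are identified; `growthOffsetCorrection()` anchors the
abundance-weighted mean fitness at the first passage to a declared
baseline (default 0.5/day, a typical in-vitro net growth rate).

**Stage 2 — one-step neighbors.** For each viable karyotype one
missegregation from S, the expected frequency obeys

dxᵢ/dt = Σⱼ P(i|j) fⱼ xⱼ(t) + (fᵢ − φ(t)) xᵢ(t),

influx from frequent parents plus the neighbor's own relative growth.
The mean-fitness term φ(t) is not optional decoration: without it the
frequency variable grows at an absolute rate and the predicted
trajectories overflow any bounded frequency on adapted populations,
which in practice turns every unobserved neighbor into an extreme
outlier. P(i|j) is the per-division missegregation transition
probability (`daughterKernel()`: daughter copy number n + 2g − m with
m ~ Bin(n, p), g ~ Bin(m, ½); whole-karyotype transitions are products
over chromosomes). The neighbor fitness maximizes a binomial likelihood
of its observed counts plus a normal prior N(fᵢ − fⱼ | μ_δ, σ_δ²) per
distance-1 frequent parent. Defaults μ_δ = 0, σ_δ = 0.1/day: zero prior
drift, and a prior scale matching the fitness dispersion we observe
among frequent clones in both synthetic and reported experimental fits.
Zero observed counts cap a neighbor's fitness — absence is evidence —
which also means estimates for deleterious neighbors are upper bounds
more than point estimates.

The assumed inference rate *p* defaults to 7.5×10⁻⁴ per copy per
division, a deliberately conservative literature-scale value. Inferred
neighbor slopes are coupled to it: a larger assumed *p* predicts more
influx and hence penalizes absence harder. The deterministic flux model
ignores drift — most newly founded neighbor lineages die by chance in
finite passaged populations — so assuming the full biological rate
over-predicts neighbor frequencies; the conservative default
compensates, and the parameter is exposed in `inferenceConfig()`.

**Stage 3 — interpolation.** All anchors (frequent + neighbor) feed an
ordinary-Kriging Gaussian process: Matérn ν = 3/2 covariance on
Euclidean distance in raw copy-number space, single isotropic
length-scale and variance fitted by marginal likelihood (on a
deterministic ≤200-anchor subsample for large anchor sets; the final
weights always use every anchor), fixed nugget (default 10⁻⁴
(fitness/day)², i.e. 0.01/day observation noise), constant GLS mean.
The fitted surface is tabulated over the charted region — every viable
karyotype within `radius = 2` missegregations of S.

**Stage 4 — internal consistency.** Each frequent anchor is left out and
re-predicted (exact closed-form LOO residuals at fixed hyperparameters);
the CV score is the predictive R² over those anchors: at most 1,
negative when the landscape model beats nothing. Following the method's
own model-selection rule, `fitKaryotypeLandscape()` can sweep `minObs`
over a grid (default 10/20/40) and keep the CV-maximizing fit.

**Stage 5 — forecasting.** The fitted look-up table drives the
agent-based model forward from the last observed composition;
replicate-averaged frequencies at the horizon are the forecast.
Karyotypes leaving the charted region are lethal by default (consistent
with the truncation that defines the region); `min_fitness` and
`nearest_anchor` policies are available.

## The simulator and the synthetic study conditions

The ABM is a discrete-time binomial-thinning scheme: in a step of dt
days a cell of fitness f divides with probability f·dt (dies with
probability |f|·dt when f < 0); divisions resolve missegregation
per copy; zero-copy daughters die. Serial passaging triggers at capacity
N_max, reseeding n_seed cells by multinomial down-sampling, which
reproduces the repeated bottlenecks of cell culture. A Gillespie-exact
scheme was rejected: at N ~ 10⁴–10⁵ cells the thinning approximation at
dt = 0.1 day is far below sampling noise, at a fraction of the cost.

Ground-truth landscapes are Gaussian random fields built by random
plane-wave synthesis: f(**k**) = offset + (amplitude/√n_basis)·
Σⱼ sin(2π⟨**k**, uⱼ⟩/λ + φⱼ) with uniform unit directions uⱼ in 22-D.
The wavelength λ (Euclidean copy-number units) sets smoothness; the
marginal variance converges to amplitude²/2. Defaults offset 0.5/day and
amplitude 0.3/day put founder fitness near one division every two days
with realistic ±0.2/day terrain. Covariance-matrix sampling over an
enumerated neighborhood would fix the covariance exactly but costs
O(N²)–O(N³) in the region size; plane waves evaluate anywhere in O(n_basis).

The `smooth_grf` preset (λ = 2.0; `rugged_grf` uses λ = 0.4) runs
p = 0.002 per copy per division — within the range reported for
chromosomally unstable lines — at N_max = 10⁴, n_seed = 10³, with
500-cell sampled observations every 15 days (the typical
passage-to-sequencing cadence); the eight observations at days 15–120
form the training window and later observations are forecasting
targets. These are the study conditions for all synthetic validation;
they were chosen once, from the biology, and the validation statistics
(`syntheticValidation()`) are reported under them.

What the generator does *not* emulate: doublet/quality artifacts in
single-cell calls, segmental aneuploidy, whole-genome-doubling events as
a distinct mechanism, cell-cell interactions, and time-varying
landscapes. Passing synthetic validation therefore demonstrates correct
inference under the stated model, not robustness to those real-data
complications.

## Forecast metrics

Population change vectors are differences of frequency-weighted mean
karyotypes between timepoints (the 22-D centroid; other embeddings can
be supplied since the angle operates on bare vectors). The angle metric
is arccos of their cosine similarity; a Monte Carlo null draws matched
numbers of angles between independent Gaussian unit vectors in 22-D
(median 90°) and compares the median of per-unit medians. Distributional
error uses exact discrete Wasserstein-1 with Euclidean ground metric
(Manhattan selectable), solved by a transportation simplex in compiled
code and cross-checked in tests against an independent quadratic-program
oracle; the static no-evolution baseline (predict the last observed
state) is the reference a useful forecast must beat.

## Downstream analyses

Δf profiles collect the 44 one-step fitness effects around a karyotype
(NA for losses into zero-copy states); profile similarity uses Pearson
correlation with Fisher-z transform. WGD status is modal copy
number ≥ 3. Group contrasts of per-fit mean effects use a permutation
Kolmogorov–Smirnov test with labels permuted at the landscape-fit level
(avoiding pseudo-replication). Emergence of novel karyotypes is modeled
by logistic regression on landscape fitness and the fractions d₁–d₅ of
the current sample within 1–5 missegregations (cell-weighted by
default; clone-weighted selectable). Passage-disjoint trajectory sets
for resampling are drawn by random root-to-terminal walks with node
removal.

The missegregation-rate screen builds a growth-weighted transfer
operator over the charted region, A(i,j) = P(i|j; p)·exp(fⱼ·dt), with
off-region flux truncated and the *mutation kernel* renormalized per
parent. The growth factor itself must stay unnormalized — making the
full operator column-stochastic divides exp(fⱼ·dt) out exactly and
deletes selection from the dynamics — so the steady state is the Perron
eigenvector, computed by repeated matrix squaring for small systems
(robust to the O(p) spectral gaps at low rates) or power iteration for
large ones. Dominance switches across rates, and the x/y
(low-rate/high-rate dominant) group assignment by the sign of the
frequency-rate correlation, reproduce the quasispecies error-threshold
phenomenology: the bundled `two_peak_toy` landscape (narrow peak at
fitness 1.0/day vs a broad 0.8/day plateau) switches dominants at a few
percent missegregation per copy per division.

## Numerical choices and edge cases

- Transition enumeration in the transfer operator stops at Manhattan
  distance 2 (default): at plausible rates, ≥3-chromosome events carry
  probability O((Cp)³) and are far below the kernel tail that matters.
  The quadratic enumeration caps at 4000 states.
- The neighbor ODE is integrated by trapezoidal quadrature on a ~120-node
  grid containing the observation times exactly; integrating-factor
  exponentials are shift-normalized and capped so extreme trial fitnesses
  clamp instead of overflowing (clamped trajectories are rejected by the
  likelihood anyway).
- The transportation simplex perturbs supplies by ~10⁻¹¹ deterministic
  increments to break degeneracy; costs are exact to ~10⁻¹⁰.
- Replicator evaluations keep frequencies on the simplex to 10⁻⁹ by
  construction (softmax form).
- Degenerate inputs fail loudly: empty frequent sets, zero-variance
  anchors, off-simplex initial frequencies, cyclic lineage graphs, and
  unknown landscape source tags are errors; zero-variance CV and
  zero-direction angles return flagged `NaN` with a warning.

## Problem sizes

Unit tests run on toy systems (≤ 6 clones, ≤ 3-state chains, 10³–10⁴
cells); the synthetic validation uses 10–20 replicates of the
`smooth_grf` conditions above, Monte Carlo oracles use 10⁵–10⁶ draws,
and calibration studies 100–200 replicates. These sizes were chosen so
that each statistical check has the power its tolerance implies.

## Known limitations

- Fitness is assumed static over the observation window and intrinsic to
  karyotype; treatment switches or microenvironmental drift during the
  window will be absorbed into (biased) fitness estimates.
- Neighbor fitness estimates inherit the deterministic-flux
  approximation; for rarely observed neighbors they are regularized
  upper bounds, biased toward the parent by the prior.
- The missegregation kernel treats chromosomes independently and
  identically; allele-specific karyotypes and chromosome-specific error
  rates are out of scope.
- The quadratic transition-matrix enumeration limits rate screens to
  regions of a few thousand karyotypes; larger fitted regions need the
  screen restricted to their most abundant states.
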