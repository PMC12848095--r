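Package: karyofit
Title: Inference and Simulation of Karyotype Fitness Landscapes from
    Longitudinal Single-Cell Copy-Number Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers local karyotype fitness landscapes from longitudinal
    single-cell karyotype counts and uses them to forecast the evolution of
    aneuploid cell populations. Fitness of frequently observed karyotypes is
    estimated from replicator dynamics of clone frequencies, extended to
    one-missegregation-step neighbours via a mutational-flux model, and
    interpolated across the charted region of karyotype space with
    Matern-kernel Gaussian-process regression (Kriging), with a
    leave-one-out cross-validation score as an internal consistency check.
    Includes an agent-based model of dividing cells with per-copy chromosome
    missegregation and serial passaging, Gaussian-random-field ground-truth
    landscape generation for validation, forecasting metrics (angle metric
    with Monte Carlo null, exact discrete Wasserstein-1 distance, overlap
    coefficients, no-evolution baseline), and downstream analyses of fitted
    landscapes (one-step fitness-effect profiles, whole-genome-doubling
    contrasts, emergence prediction of novel karyotypes, and
    quasispecies/error-threshold steady-state screens across missegregation
    rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
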