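Package: msmpipe
Title: Markov State Model Inference for Short-Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates Markov state models from ensembles of short
    molecular trajectories: subset-RMSD conformational metrics, greedy K-center
    microstate clustering, transition-matrix estimation with implied-timescale
    and Chapman-Kolmogorov validation, PCCA+ lumping into metastable
    macrostates, and mean first passage times by linear solve, Monte-Carlo
    first-passage regression, and a weighted upper bound. Includes an
    overdamped Langevin / steered-pull synthetic trajectory generator with
    exact discrete-chain ground truth, population-density (-ln P) landscapes
    with block convergence tests, and trajectory-mapping slow-mode analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
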