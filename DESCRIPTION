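Package: critperturb
Title: Critical Lattice Simulation and Perturbation-Response Analysis of
    Neuronal Spike Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional excitable cellular-automaton
    network of cortical layer 2/3 with distance-dependent connectivity and
    a tunable branching parameter, and analyses single-neuron
    perturbation experiments on spike-count rasters: responder
    classification with false-discovery-rate control, power-law
    response-scaling fits, mean-matched Fano factors, scale-invariant
    neuronal-avalanche statistics with temporal coarse-graining, and
    decoding of the perturbation origin with Shapley-guided feature
    elimination. Includes a synthetic-recording generator with planted
    ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    xgboost,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
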