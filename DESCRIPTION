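Package: popsync
Title: Noise-Induced Synchronization of Stochastic Neuronal Population Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how common extrinsic noise synchronizes, and
    intrinsic finite-size noise desynchronizes, ensembles of uncoupled
    neuronal population oscillators. Implements birth-death master-equation
    models whose mean-field limit is the Wilson-Cowan rate equations, their
    chemical-Langevin approximation with multiplicative intrinsic and common
    extrinsic noise, exact stochastic simulation (Gillespie and
    piecewise-deterministic thinning for a synaptic-depression hybrid model),
    limit-cycle location, adjoint phase-resetting curves, stochastic phase
    reduction with Ito/Stratonovich bookkeeping, and the averaged stationary
    distribution of pairwise phase differences with its Cauchy approximation,
    peak/cluster detection and histogram comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
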