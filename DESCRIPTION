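Package: lmnet
Title: Leaky Markovian Networks: Master Equations, Landscape Thermodynamics
    and Avalanche Statistics
Version: 0.1.0
Authors@R:
    person("lmnet", "developers", email = "lmnet@example.org", role = c("aut", "cre"))
Description: Tools for exact probabilistic analysis of leaky Markovian
    networks: coarse-grained binary-node population models with leak and
    input-dependent transition propensities. Builds sparse master-equation
    generators on the lattice of active-count vectors, solves stationary and
    transient distributions, computes potential energy landscapes and the
    associated thermodynamic summaries (internal and free potential energy,
    entropy, self-information, pressures, bulk modulus) as a function of
    network size, and detects the critical network size at which the ground
    state reallocates to the inactive origin. Includes the macroscopic ODE
    limit with linear noise approximation, exact Gillespie simulation,
    threshold- and bin-based avalanche detection with power-law diagnostics,
    size-duration scaling and avalanche shape collapse, and ready-made
    SISa-epidemic and excitatory/inhibitory neural-network model builders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
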