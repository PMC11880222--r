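Package: pbpktemplate
Title: Configurable PBPK Model Template Simulator and Implementation
    Timing Experiments
Version: 0.1.0
Authors@R:
    person("Template", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    model "template": a single configurable ODE superstructure with 53
    state variables and 105 output variables from which chemical-specific
    models are obtained by switching compartments, metabolic pathways,
    exposure routes and representation options on or off.  Ships
    stand-alone dichloromethane and chloroform models for equivalence
    checking, four canonical exposure scenarios (constant and periodic,
    inhalation and oral), seeded Monte-Carlo virtual human populations,
    a compiled adaptive Runge-Kutta integrator with bolus-dose event
    handling, and a CPU-time benchmarking harness covering eight
    model-implementation choices (template vs stand-alone, conditional
    operator vs multiplicative switches, output grid density, output-map
    size, body-weight handling, state pruning, blood and gas-exchange
    representation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'params.R'
    'config.R'
    'exposure.R'
    'engine.R'
    'simulate.R'
    'population.R'
    'benchmark.R'
    'pbpktemplate-package.R'
    'RcppExports.R'
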