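Package: nadtherm
Title: Temperature-Dependent Kinetic Modelling of Bacterial NAD Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of the two bacterial NAD salvage routes (the
    four-step PncA/Preiss-Handler pathway and the two-step Nampt pathway)
    under temperature stress. Fits Arrhenius parameters to measured
    non-enzymatic hydrolysis rates of pyridine intermediates, builds a
    moiety-conserved ODE model of the reaction network with
    Arrhenius-scaled rate laws, solves it to steady state with a compiled
    pseudo-transient/Newton solver, accounts ATP cost per NAD produced,
    optimizes enzyme allocation under resource constraints with an
    evolutionary-programming algorithm, and computes concentration control
    coefficients by metabolic control analysis. Includes seeded synthetic
    data generators so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
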