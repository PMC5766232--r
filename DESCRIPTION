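Package: remyelin
Title: Conduction Velocity in Segmentally Remyelinated Myelinated Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study how randomly placed, shortened (remyelinated)
    internodes slow saltatory conduction in myelinated axons. Provides a
    synthetic axon-layout generator with binomial remyelination, a discrete
    cable simulator with pluggable Hodgkin-Huxley nodal dynamics, closed-form
    velocity theory (harmonic-mean benchmark velocity, square-root internode
    length scaling, a perturbative transition-delay estimator and composite
    travel-time estimates), and an ensemble study pipeline that compares
    simulated conduction velocities against the analytical benchmarks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
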