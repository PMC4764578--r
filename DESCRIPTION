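Package: thymokin
Title: Kinetic Modeling of Thymocyte Beta-Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-compartment linear ordinary-differential-equation model of
    thymocyte development through beta-selection (DN3, DN4, immature CD8
    single-positive, and double-positive stages) with constant progenitor
    influx, per-stage differentiation and turnover rates, exact steady-state
    and closed-form transient solutions, a matrix-exponential solver for the
    general case, a numerical ODE integrator and an exact stochastic event
    simulator for independent verification, a synthetic flow-cytometry
    subset-count generator emulating steady-state cross-sections and
    anti-CD3-triggered time courses in recombination-deficient mice, and a
    multi-start least-squares stage for recovering the rate constants from
    observed subset counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
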