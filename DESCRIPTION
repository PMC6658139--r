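Package: commsel
Title: Individual-Based Simulation of Artificial Selection on Two-Species
    Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid deterministic/stochastic simulator of artificial selection
    on Helper-Manufacturer microbial communities. Tracks individual cells
    (biomass growth, division, stochastic death, phenotype-altering mutation
    with a bilateral-exponential effect distribution and optional
    diminishing-returns epistasis) coupled to batch-culture chemical dynamics
    (Monod and dual-substrate Mankad-Bungay kinetics), implements the
    community-reproduction schemes of serial propagation experiments
    (volumetric pipetting, biomass or cell-number sorting, fixed-fold
    dilution) and intercommunity selection strategies (top-dog, top-tier,
    random control), and provides the deterministic ODE-level analyses
    (community-function landscape, steady-state composition, monoculture
    optimum, Newborn fluctuation statistics) used to interpret selection
    dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
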