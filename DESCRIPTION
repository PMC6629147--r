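Package: rmimmunity
Title: Multi-Scale Models of Restriction-Modification Immunity in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models bacterial innate immunity conferred by restriction-modification
    (RM) systems across biological scales. Builds the absorbing Markov chain for
    methylation dynamics at a single restriction site and computes phase-type
    waiting times to self-restriction together with the quasi-stationary
    methylation distribution of surviving lineages. Propagates these single-cell
    quantities to population-level self-restriction rates and effective growth
    rates with enzyme-expression costs and multiple RM systems, and validates the
    analytics with an exact Gillespie simulation of a growing, self-restricting
    population. Provides the phage-escape probability, the closed-form law of the
    time to first phage escape under an inhomogeneous Poisson encounter process,
    population-performance metrics, deterministic bacteria-phage ecology with
    susceptible and methylated phage, and Pareto-front analysis of the
    cost-efficiency tradeoff including constrained optimization of enzyme
    activities and an E. coli/EcoRI calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
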