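Package: sirsring
Title: Absorbing-State Phase Transitions of a Synchronous SIRS Automaton
    on a Ring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the synchronous Susceptible-Infected-Refractory-
    Susceptible (SIRS) cellular automaton on a one-dimensional periodic
    lattice and analyses its two absorbing-state phase transitions.  The
    model has a low-infectivity threshold with directed-percolation
    scaling and a high-infectivity threshold where the transition is
    discontinuous.  Tools are provided for realization ensembles,
    steady-state scans, trapped-configuration classification, power-law
    fits of the order-parameter exponents, quasistationary cell-occupancy
    histograms, variance-peak finite-size extrapolation of the upper
    threshold, and space-time diagram export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
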