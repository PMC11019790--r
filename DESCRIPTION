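Package: syncomfba
Title: Community Dynamic Flux Balance Analysis for Synthetic Bacterial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of small synthetic bacterial communities
    assembling under nutrient-rich serial passaging. Implements stoichiometric
    model handling with flux balance analysis (FBA) and parsimonious FBA on a
    built-in simplex solver, well-mixed batch dynamic FBA with growth-dilution
    cycles, a coarse-to-fine calibration of limiting-nutrient uptake rates
    against a reference community composition, inference of candidate
    interspecies metabolite-exchange networks from integrated secretion and
    uptake fluxes, generalized Lotka-Volterra simulation and fitting for
    interaction-sign classification, growth-curve statistics, and a generator
    of toy three-species communities with planted cross-feeding topology for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    deSolve,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
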