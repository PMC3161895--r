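Package: pbmcell
Title: Population Balance Modelling of Stochastic Gene Expression in Cell Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ensembles of chemical-Langevin single-cell gene
    regulatory models coupled through a shared extracellular inhibitor
    balance (a sample-path population balance model), together with the
    contrasting isolated single-cell stochastic model, deterministic
    steady-state and bistability analysis, and population distribution
    diagnostics. Ships the pheromone-inducible pCF10 conjugation switch of
    Enterococcus faecalis and a minimal toy gene circuit, and demonstrates
    that deterministic bistability is neither necessary nor sufficient for a
    bimodal protein distribution across a population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    tibble
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
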