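Package: gblupsim
Title: Forward Breeding-Programme Simulation and Single-Step Genomic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of a beef-cattle breeding programme
    (historical population with drift and recurrent mutation, expansion phase,
    and recent generations under phenotypic or EBV-based selection with
    truncation replacement), together with pedigree BLUP, GBLUP and weighted
    single-step GBLUP (ssGBLUP) genetic evaluation.  Prediction accuracy is
    derived from the prediction error variance of the mixed-model equations.
    Includes a pedigree-error injection harness and a scenario runner that
    sweeps selection method, heritability, marker density, training-population
    size, blending weight and pedigree-error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    methods,
    tibble,
    generics
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
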