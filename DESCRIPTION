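Package: akinetics
Title: Single-Molecule Kinetic Analysis of Adenylate Kinase Domain Motions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hidden Markov modelling of nanopore current recordings of
    adenylate kinase. Implements a ten-state ligand-gated continuous-time
    Markov chain with grouped Gaussian emissions, a scaled forward-algorithm
    likelihood, bounded maximum-likelihood estimation of transition rates
    with multistarts, comparison of endosteric model variants, and
    simulation-based prediction of aggregate LID/NMP domain closing and
    opening rates. Also provides a synthetic nanopore-trace generator,
    current-trace segment selection, all-point histograms, level
    idealization and dwell-time analysis, and Hill / linear / one-site
    dose-response fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
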