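Package: pepdca
Title: In Silico Evolution of Bicyclic Peptide Inhibitors by Direct
    Coupling Analysis, Monte Carlo Sampling and Random-Forest Affinity
    Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a Potts model to a small fixed-length peptide family by
    regularized pseudolikelihood maximization (plmDCA), generates novel
    scaffold-constrained sequences by Metropolis Monte Carlo on the model
    score landscape, ranks and filters them with a random-forest regressor
    of inhibition constants (Ki), and distills the surviving pool into
    position-frequency logos and consensus design candidates. Includes a
    leave-out recovery harness and a synthetic-data module (planted Potts
    models, exact Boltzmann enumeration, affinity landscapes) so every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    randomForest,
    Biostrings,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
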