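Package: ghostabc
Title: Ghost Archaic Introgression Inference by ABC with Deep-Learning
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic inference of archaic "ghost" introgression into
    African populations using Approximate Bayesian Computation with
    deep-learning summary statistics (ABC-DL). Provides six competing
    demographic models of African and archaic-hominin history with prior
    specifications, a fragment-based structured coalescent simulator for a
    seven-genome panel, the multidimensional unfolded joint site frequency
    spectrum (jSFS) with noise injection, ensembles of feed-forward networks
    whose averaged predictions serve as summary statistics, rejection ABC
    for model choice and parameter estimation, confusion-matrix and
    factor-2 self-consistency validations, and descriptive population
    statistics (pairwise differences per kbp, runs of homozygosity,
    ABBA-BABA D-statistics and f4-ratios with weighted block jackknife).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
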