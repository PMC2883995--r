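Package: semap
Title: Semantic Cognitive Maps from Synonym-Antonym Dictionaries
Version: 1.0.0
Authors@R:
    person("Semap", "Developers", email = "semap-dev@example.org",
           role = c("aut", "cre"))
Description: Builds low-dimensional semantic maps from dictionaries of
    synonyms and antonyms. Word relations are distilled into a signed
    graph whose "core" is embedded in a d-dimensional space by minimizing
    a quartic pairwise energy (annealed gradient descent or damped
    Newton), then rotated to principal components, sign-standardized
    against anchor words and rescaled. Includes per-word and per-pair
    analytics (angle distributions, dot-product synonym/antonym
    classification, axis rankings, connotation octants, frequency-weighted
    concept means), cross-map statistics (PC correlation matrices,
    canonical correlation analysis, an overall correlation coefficient
    built from covariance-matrix norms), a capture-recapture estimate of
    dictionary coverage, and a self-contained color-sphere simulator used
    to validate map reconstruction against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
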