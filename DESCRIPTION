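Package: phylopred
Title: Bayesian Phylogenetic Prediction and Evolutionary Singularity Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether a focal lineage is an evolutionary singularity for
    a continuous trait, given an allometric predictor and a phylogeny. Fits a
    phylogenetic generalized least squares (PGLS) regression under a
    Brownian-motion covariance with Pagel's lambda branch-length scaling,
    samples regression parameters, residual variance, lambda and tree
    identity by Markov chain Monte Carlo over a set of randomly resolved
    phylogenies, and derives the posterior-predictive distribution of the
    trait for a focal tip whose data were withheld from fitting. The focal
    species is flagged as a singularity when its observed value falls outside
    the 95% credible interval of that predictive distribution. Includes trait
    preprocessing (brain mass to volume conversion, species means across
    literature sources, within-species repeatability with bootstrap
    confidence intervals), tree editing (tip grafting, random polytomy
    resolution), maximum-likelihood lambda profiling, a synthetic-data
    generator for end-to-end calibration, and pipeline drivers for
    allometry, single-focal and multi-breed analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    coda,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
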