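Package: scartree
Title: Time-Scaled Cell Phylogenies and Population Dynamics from Lineage Recorder Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian phylogenetic inference of time-scaled single-cell trees
    from genetic lineage tracing (CRISPR scarring) barcodes. Implements a
    time-dependent editing substitution model with closed-form transition
    probabilities, a pruning-algorithm tree likelihood with origin
    conditioning, a constant-rate birth-death-sampling tree prior, and
    Metropolis-Hastings MCMC for joint estimation of trees, editing rates and
    cell population dynamic parameters, optionally pooled across experimental
    replicates. Includes a Gillespie simulator of birth-death trees and
    barcode evolution, well-calibrated validation machinery, and parameter
    recovery and tree-topology scoreboards.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
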