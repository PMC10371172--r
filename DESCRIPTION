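Package: chancluster
Title: Ion-Channel Cluster Self-Assembly, Morphometry, Coupled Gating,
    and Delayed-Rectifier Current Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how voltage-gated ion channels organize
    into surface-membrane clusters and what that organization does to
    channel function. Includes a stochastic lattice model of cluster
    self-assembly (nucleation, growth, removal) with exponential
    size-distribution fitting and simulation-based parameter recovery;
    seeded generators for synthetic super-resolution localization
    fields, confocal-like image stacks and fluorescence sparklet traces
    with known ground truth; cluster segmentation and morphometry
    (macro/micro classification, membrane-overlap restriction,
    resolution-matching Gaussian blur, puncta density); coupled
    Markov-chain analysis of Ca2+ sparklet records (quantal
    idealization, nPs activity, maximum-likelihood coupling coefficient
    kappa with bootstrap intervals); and a Hodgkin-Huxley-type
    delayed-rectifier K+ current model with functional-fraction scaling,
    conductance calibration and blocker-subtraction utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
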