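Package: ratelink
Title: Detecting Correlated Rates of Molecular and Morphological Evolution
Version: 0.1.0
Authors@R:
    person("Ratelink", "Developers", email = "ratelink@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for evaluating statistical
    methods that detect correlated rates of molecular and morphological
    evolution on phylogenies. Provides an uncorrelated relaxed-clock
    simulator for generating coupled or independent molecular and
    morphological phylograms on ultrametric chronograms, sequence and
    discrete-character simulators (GTR+G+I and Mk+G), fixed-topology
    maximum-likelihood branch-length estimation with linked
    ("proportionate") and unlinked branch-length models, Bayesian
    relaxed-clock MCMC with generalized stepping-stone marginal-likelihood
    estimation, five detection tests (root-to-tip distance correlations,
    independent sister-pairs contrasts, likelihood-based model selection,
    correlations of Bayesian branch rates, and Bayesian model selection),
    and an evaluation harness that measures power and false-positive rates
    over a factorial simulation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
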