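Package: moltevol
Title: Phylogenetic Comparative Analysis of Correlated Binary Trait Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian comparative analyses of binary traits on
    phylogenies, motivated by studies of plumage molt evolution in passerines.
    Implements a Bayesian phylogenetic mixed model for binary responses
    (latent-liability MCMC with a parameter-expanded prior on the phylogenetic
    variance, fixed residual variance, pMCMC and heritability reporting),
    Pagel's dependent and independent models of correlated evolution for two
    binary characters (Felsenstein pruning over the four joint states,
    reversible-jump MCMC with a zero class, stepping-stone marginal
    likelihoods, Bayes factors, contingent-change and temporal-order tests),
    multi-tree and multi-run aggregation, dichotomization sweeps, and a
    synthetic-data generator covering ultrametric trees, jointly evolving
    binary trait pairs, and liability-model trait tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
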