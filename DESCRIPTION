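Package: phenotrans
Title: Transition-Rate Analysis of Discrete Symbiont-Induced Phenotypes on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of a five-state discrete trait (symbiont-induced
    host reproductive phenotypes: cytoplasmic incompatibility, feminization,
    male killing, parthenogenesis induction, other) evolving on a phylogeny
    under continuous-time Markov (Mk-type) models. Provides a pruning-algorithm
    likelihood engine with brute-force oracles, maximum-likelihood fitting of
    an eight-model rate family with threshold-and-bin model reduction and AIC
    selection, two phylogenetic-signal tests (star-tree AIC comparison and a
    Sankoff minimum-transitions permutation test), a reversible-jump MCMC over
    rate-class partitions with Bayes factors per model and per parameter-count
    class, marginal ancestral-state estimation at tagged clades, cross-method
    rate standardization and rank synthesis, and a synthetic-data generator
    (Yule trees, Gillespie trait simulation, a Wolbachia-like preset) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
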