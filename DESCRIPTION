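Package: iteem
Title: Individual-Based Eco-Evolutionary Dynamics in Interaction Trait Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based simulation of well-mixed communities
    whose members evolve in interaction trait space under a life-history
    trade-off between replication probability and competitive ability.
    Strains are rows of a reciprocal pairwise survival-probability matrix;
    mutants inherit perturbed copies of the parental row, and a one-parameter
    trade-off curve converts mean competitive ability into fecundity. The
    package bundles the analysis stack needed to characterise the emerging
    communities: dominance networks and intransitive (rock-paper-scissors)
    cycle statistics with randomised-ensemble normalisation, functional
    diversity via minimum spanning trees in trait space, species clustering
    and classical multidimensional scaling, lineage tracking with Newick and
    Muller-plot exports, a deterministic Lotka-Volterra mean-field
    counterpart, speciation and extinction event statistics with a
    Poisson-process bootstrap test, a neutral-model baseline, and sweep
    orchestration for diversity phase diagrams over trade-off shape and
    lifespan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    deSolve,
    vegan,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
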