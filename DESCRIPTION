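Package: ccsnet
Title: Network Reconstruction from Evolutionary-Game and Oscillator
    Dynamics by Combined Compressed Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs undirected, unweighted networks from observed node
    dynamics. Simulates evolutionary prisoner's-dilemma games (five strategies
    with Fermi imitation updates) and coupled Kuramoto oscillators on synthetic
    or user-supplied graphs, then recovers each node's neighborhood by sparse
    recovery: an exact 0-1 program solved by branch-and-bound over an
    authored bounded-variable simplex (ICS), a concave quadratic program
    driven to polytope vertices by successive linearization (QCS), L1 basis
    pursuit (CS), and non-negative LASSO. A combined pipeline (CCS) selects
    the solver per node from sample-capacity thresholds and a payoff-variance
    index that identifies hubs, and evaluation tools score reconstructions
    (success rate, AUROC, AUPR), node-level correct-recovery frequencies, and
    payoff-diversity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    pROC,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
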