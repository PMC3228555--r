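Package: netgem
Title: Temporal Dynamics of Gene Interaction Networks from Short
    Expression Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers time-varying interaction strengths on a known
    gene-interaction network from short temporal gene expression series.
    Edge weights evolve as a hidden Markov chain whose transition matrix is
    a mixture of functional-category transition matrices with Dirichlet
    priors; parameters are estimated by expectation-maximization with
    per-edge forward-backward recursions that are linear in the number of
    time points. Knockout strains are handled by deterministic damping of
    edge weights around the perturbation. Includes the Ising-model Gibbs
    simulator used to benchmark the method on Erdos-Renyi networks,
    change-score statistics with exponential-tail significance selection,
    trace-based hypothesis tests, and ROC/AUC evaluation against simulated
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
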