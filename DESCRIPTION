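Package: causnet
Title: Sparse Lagged Regression and Granger-Causality Inference of Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers signed, directed gene regulatory networks from short
    replicated time-course expression data using a three-stage procedure:
    exhaustive best-subset sparse linear regression on time-lagged
    expression (with an optional virtual time shift that wraps the last
    sampling time onto the first to capture overnight regulation), an
    F-test of Granger causality that removes regulators without
    significant marginal contribution, and a truncated-Gaussian
    perturbation analysis (a Gaussian approximation of bootstrapping over
    biological replicates) whose repeated reconstructions yield per-edge
    existence and sign confidence weights. Includes a generative simulator
    of the underlying discrete-time linear-Gaussian expression model with
    sparse signed ground-truth networks, recovery metrics (precision,
    recall, F1, sign accuracy, AUPR) against the simulated truth, and
    Cytoscape-ready SIF and GraphML export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
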