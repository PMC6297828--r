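Package: cloneattractor
Title: Clone-Attractor Analysis of T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Longitudinal T-cell receptor (TCR) repertoire analysis through
    Clone-Attractors: greedy weighted-edit-distance clustering of CDR3
    amino-acid sequences into clusters with medoid representatives,
    per-sample/time-point repertoire graphs with discriminative topology
    statistics (Molecular Topological Index, thresholded betweenness
    centrality), power-law characterization of cluster sizes, and a
    two-stage kernel-classifier ensemble with forward feature selection
    and noise-robustness evaluation. Includes a seeded synthetic
    longitudinal repertoire generator and matching of cluster
    representatives against public TCR sequence tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    igraph,
    e1071,
    pROC,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
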