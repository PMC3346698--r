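Package: pathcolor
Title: Topology-Aware Color-Coding and Bounded A* Search for Signaling
    Pathway Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects candidate signaling pathways as minimum-weight simple
    paths in protein-protein interaction networks weighted by gene
    co-expression (edge weight -log |Pearson r|).  Implements a
    topology-aware color-coding scheme in which hubs and articulation
    points are forced to differ in color from their neighbours, a bounded
    A* (depth-first branch-and-bound) search for colorful,
    cellular-location-monotone paths of fixed length, bound calibration
    from sampled path statistics, KNN imputation of missing expression
    values, precision/recall/F evaluation against reference main-chain
    pathways, hypergeometric enrichment scoring, and a synthetic-data
    generator (scale-free networks with planted high-correlation paths)
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
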