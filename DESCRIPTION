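Package: acnet
Title: Learning Causal Biological Networks by Parallel Ant Colony Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-and-search structure learning of causal biological networks
    (directed acyclic graphs over biological signal variables such as brain
    regions or signalling proteins) from one or more observational data sets.
    Each data set is searched by its own ant colony under the K2 Bayesian
    scoring metric with a mutual-information-weighted heuristic; colonies
    exchange information through pheromone fusion at iteration barriers and the
    final network is extracted by majority vote over the colony-best graphs.
    Includes a linear structural-equation benchmark generator with
    upper-triangular random ground-truth graphs, equal-frequency
    discretization of continuous signals, and directed-graph recovery metrics
    (precision, recall, F1, structural Hamming distance).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
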