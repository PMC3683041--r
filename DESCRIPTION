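Package: prognet
Title: Exact Score-Based Learning of Progression Networks from
    Cross-Sectional Binary Aberration Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns k-bounded Bayesian networks and monotone or
    semi-monotone progression networks from cross-sectional binary data
    such as tumor copy-number aberration calls. Builds a weighted
    selector hypergraph of candidate parent sets scored by maximum
    likelihood or BIC, formulates maximum-weight acyclic subhypergraph
    selection as an integer program with ordering-based acyclicity
    constraints, and solves it exactly with a dynamic-programming or
    branch-and-bound backend. Includes a forward-sampling simulator for
    random progression networks, structure-recovery metrics (recovered
    edge percentage, relative symmetric difference, FDR/FNR, bad-edge
    percentage against a reference partial order), and an epsilon
    calibration procedure.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
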