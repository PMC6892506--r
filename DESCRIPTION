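Package: regomax
Title: Reduced Google Matrix Analysis of Directed Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the effective interactions between a small set
    of nodes of interest embedded in a large directed network, following the
    reduced Google matrix (REGOMAX) approach. Provides sparse, matrix-free
    Google matrix construction with PageRank and CheiRank centralities, the
    reduced Google matrix and its decomposition into direct, PageRank-dominated
    and indirect ("hidden link") components, PageRank sensitivity to individual
    link perturbations, iterative friendship-network extraction, rank
    statistics (relative ranks, Spearman correlation, top-j overlap, rank-plane
    densities), and a generator of synthetic Wikipedia-like layered networks
    for testing every pipeline stage at desk scale. Inputs and outputs are
    tidy tibbles; results carry broom-style tidy() and glance() methods and
    ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    utils,
    stats,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork,
    withr
Config/testthat/edition: 3
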