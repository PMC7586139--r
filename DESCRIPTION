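Package: toposom
Title: Topographic Maps of High-Dimensional Structure from 2-D Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses how faithfully a two-dimensional projection (PCA, t-SNE,
    UMAP, or any other dimensionality-reduction method) represents the
    distance structure of the original high-dimensional data. A simplified
    emergent self-organizing map (sESOM) is trained on a toroidal lattice with
    best-matching units fixed from the projection, the generalized U-matrix of
    mean inter-prototype distances is computed, and the result is rendered as
    a topographic map with hypsometric tints in which valleys correspond to
    clusters, mountain ranges to cluster borders, and misplaced points to
    volcanoes. Includes generators for classic benchmark datasets (interlocked
    rings, bars-plus-outliers, sphere surface, Gaussian mixtures) and a
    valley-counting estimator of the number of clusters.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
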