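Package: funscape
Title: Attractor Landscapes, Community Simulation and Beta-Diversity
    Statistics for Microbiome Functional Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metastable attractors in the functional composition of
    microbial communities with a topological landscape analysis:
    Jensen-Shannon divergence between samples, principal coordinate
    ordination, the Mapper algorithm on the first two principal
    coordinates, and basin detection from a k-nearest-neighbour density
    potential on the Mapper graph.  Also provides an individual-based
    stochastic community simulator (Hubbell neutral dynamics and the
    self-organized instability model with pairwise interactions), Morisita
    overlap statistics on replicate pairs, gamma generalized linear models
    with AICc ranking and Akaike weights, and synthetic-data generators
    with known attractor structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
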