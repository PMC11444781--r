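Package: sirscape
Title: Pattern Formation and Tipping Points in Spatial Contagion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a generalized SIRS metapopulation model on a periodic
    lattice in which population mobility is given by maximum-entropy flows
    that respond to the local contagion state. Provides percolation-based
    classification of the resulting spatial patterns (uniform, spots,
    labyrinth, connected/chequerboard), sweeps over the risk-disposition
    plane and the susceptibility-acquisition axis with tipping-point
    detection, and an areal-interpolation pipeline that scores choropleth
    (polygon-level) data on the same percolation order parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
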