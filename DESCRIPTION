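Package: sndm
Title: Self-Normalized Density Maps for Counting Microbial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-map counting of microbial colonies on Petri-dish images.
    Converts bounding-box annotations into Gaussian density targets whose pixel
    sum equals the colony count, fits a two-level nested U-shaped convolutional
    network with deep binary cross-entropy supervision, and optionally lets the
    network rescale its own output normalization through a per-image parameter
    (beta) predicted by a bypass head from the deepest encoder features
    (the self-normalized density map, SNDM). Prediction uncertainty is
    quantified by bootstrap ensembles and Monte Carlo dropout, and counting
    quality by MAE and sMAPE with stratified and binned diagnostics. A
    synthetic Petri-dish scene generator provides annotated benchmark data at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
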