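Package: pamvasc
Title: Layered Skin Vasculature Quantification for Photoacoustic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative analysis of optical-resolution
    photoacoustic microscopy (OR-PAM) volumes of skin, aimed at longitudinal
    monitoring of microvascular change such as corticosteroid-induced
    vasoconstriction. The package detects the skin surface and flattens
    volumes to surface-referenced depth, segments the papillary dermis,
    reticular dermis, and hypodermis from the depth histogram of vessel
    voxels, computes layer-wise maximum-amplitude projections, quantifies
    vascular density over a timepoint series with an averaged-Otsu global
    threshold, tracks the depth centroid of the vascular network, and
    summarises treatment groups with means, standard errors, and paired
    t-tests. A fully parameterised synthetic skin-vasculature phantom
    generator with analytic ground truth drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
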