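Package: ladscape
Title: Phase-Field Simulation and Super-Resolution Quantification of
    Lamina-Associated Chromatin Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the mesoscale biophysics of nuclear
    chromatin organisation. Implements a reaction-diffusion phase-field
    model of heterochromatin/euchromatin segregation with
    chromatin-lamina adhesion, a quantification pipeline for 2D
    single-molecule localization data (Voronoi density segmentation,
    DBSCAN domain calling, nuclear boundary estimation and
    lamina-associated-domain thickness profiling), a synthetic
    localization generator with ground truth, and an inverse procedure
    that maps measured domain sizes to nucleus-wide distributions of
    histone methylation rates and chromatin-lamina affinities.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
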