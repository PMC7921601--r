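Package: smstoich
Title: Subunit Stoichiometry of Chaperone-Client Complexes from
    Single-Molecule Photobleaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts two-color single-molecule TIRF photobleaching data into
    subunit stoichiometries of small heat-shock protein (sHsp) chaperone-client
    complexes. Provides change-point detection of photobleaching steps on
    per-focus fluorescence trajectories, single-step intensity calibration by
    censoring-aware Gaussian fitting, fluorophores-per-point (FPP) subunit
    counting, two-channel focus detection and colocalization, one-phase
    association kinetics, rank-based size-distribution comparisons, and bulk
    aggregation-assay statistics. A synthetic-data generator embodying a
    two-step sHsp-client binding mechanism (initial capture by small sHsp
    species followed by subunit accretion) supplies ground-truth trajectories,
    complex populations, rendered two-channel movies and aggregation curves so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
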