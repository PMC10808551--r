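Package: hippotune
Title: Analysis of Two-Photon Calcium Imaging from Hippocampal Neurons on Virtual Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-photon calcium recordings of
    hippocampal interneurons and principal cells in head-fixed mice running on
    virtual tracks. Computes baseline-normalized dF/F traces (sliding-percentile
    and per-segment variants), detects calcium transients with false-positive-rate
    calibration, quantifies running-speed modulation and spatial tuning (Skaggs
    spatial information, coherence, circular vector tuning, split-half stability),
    assesses significance with circular position shuffles, classifies place cells,
    and measures between-context remapping with per-cell field correlations and
    z-scored population-vector correlations. Includes a synthetic-session
    generator with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
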