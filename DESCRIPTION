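Package: plvnet
Title: Trial-Wise Phase-Locking Connectivity and Graph Analysis for TMS-EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@plvnet.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-locked multi-trial EEG, built around
    transcranial magnetic stimulation (TMS) evoked responses. Provides a synthetic
    cohort generator with controllable cross-trial phase coupling, TMS-EEG epoch
    conditioning (pulse-artifact excision with cubic interpolation, common-average
    re-referencing, baseline correction, band-pass filtering, bad channel and trial
    handling), complex Morlet wavelet decomposition with cone-of-influence validity,
    trial-wise phase-locking value (PLV) and corrected imaginary PLV (ciPLV)
    connectivity matrices per frequency band and analysis window, weighted graph
    metrics (connectivity strength, clustering coefficient, characteristic path
    length), and paired pre/post-stimulus group statistics with Bonferroni control
    and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    tibble,
    dplyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
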