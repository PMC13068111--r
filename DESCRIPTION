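Package: ppg2ecg
Title: Reconstruct Lead-II ECG Waveforms from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-sequence reconstruction of single-lead (lead II)
    electrocardiogram waveforms from photoplethysmogram signals using a
    densely connected stack of bidirectional LSTM blocks with a per-time-step
    regression head trained under a root-mean-square-error loss. Includes the
    full training preprocessing chain (type-I linear-phase FIR filtering,
    cardiac-phase alignment by cross-correlation against the PPG upstroke,
    temporal segmentation and per-segment normalisation), an inference path
    that needs PPG only, an evaluation suite (RMSE, Pearson r, Pan-Tompkins
    R-peak detection, tolerance-free nearest-beat matching, beat-timing
    error, subject-level Student-t confidence intervals and paired Wilcoxon
    signed-rank tests), and a synthetic paired ECG/PPG cohort simulator with
    known ground truth for end-to-end testing without access to clinical
    waveform databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
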