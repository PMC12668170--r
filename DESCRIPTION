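Package: ventseg
Title: Breath Segmentation and Asynchrony Quantification for Ventilator Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects inspiratory and expiratory onsets in two-channel (airway
    pressure and flow) mechanical-ventilator waveforms sampled at 50 Hz. Provides
    a dual-head attention-gated one-dimensional U-Net trained with an
    uncertainty-weighted focal plus dice loss, two published rule-based baselines
    (flow zero crossing and derivative backtracking), tolerance-window event
    matching with precision/recall/F1, per-breath feature tables, rule-based
    classification of double-triggered and stacked breaths, Grad-CAM
    interpretability for 1-D signals, and a calibrated synthetic waveform
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
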