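Package: scgbeat
Title: ECG-Free Heartbeat Detection in Seismocardiograms by Template Matching
Version: 0.1.0
Authors@R:
    person("Paolo", "Ricci", email = "paolo.ricci@example.org",
           role = c("aut", "cre"))
Description: Detects heartbeats in seismocardiography (SCG) signals without a
    concurrent electrocardiogram, by matching a single-heartbeat template
    against the dorso-ventral acceleration signal with the normalized
    cross-correlation (NCC) and localizing NCC peaks under prominence and
    minimum-distance constraints. Includes the supporting pipeline: CSV/WFDB
    record input, zero-phase Butterworth and notch pre-filtering with
    oversampling to 1 kHz, a Pan-Tompkins reference R-peak detector for the
    ECG channel, a per-cycle true-positive/false-positive/false-negative/
    detection-error scoring scheme with sensitivity and positive predictive
    value, inter-beat-interval agreement statistics (regression, correlation,
    Bland-Altman), a synthetic SCG+ECG record generator with ground-truth
    beat times, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
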