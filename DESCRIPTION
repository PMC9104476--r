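Package: swallowEMG
Title: Swallow Detection and Fluid-Intake Estimation from Neck Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for two-channel sternohyoid surface-EMG
    recordings of swallowing: Kaiser-window FIR band-pass filtering, RMS-envelope
    burst localization and 1500 ms window extraction, a 46-feature time- and
    frequency-domain library, stepwise forward feature selection wrapped around
    leave-one-out cross-validated LDA and 1-nearest-neighbour classification of
    liquid versus non-liquid swallowing events, and per-sip fluid-volume
    estimation by a mean-sip baseline, cross-validated ordinary least squares,
    and a shallow tanh network trained by Levenberg-Marquardt. Includes a seeded
    synthetic swallow-signal generator emulating the study protocol so the whole
    pipeline is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
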