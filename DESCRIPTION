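Package: sqikit
Title: Signal Quality Control for Continuous ECG and PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of continuously recorded electrocardiogram (ECG)
    and photoplethysmogram (PPG) waveforms. Reads EDF, WFDB and delimited-text
    recordings into a common waveform container, filters and segments them,
    detects heartbeat peaks with seven interchangeable detectors, computes a
    catalogue of signal quality indices (statistical, heart-rate-variability,
    and waveform-morphology based), and classifies segments as accept or
    reject with ordered, JSON-configurable threshold rulesets. Includes a
    seeded synthetic waveform generator with ground-truth beat locations and
    controlled artifact injection, and threshold-derivation utilities
    (percentile and quantile-grid search) for building rulesets from labelled
    segment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
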