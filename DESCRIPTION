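Package: ecgpm
Title: Pattern-Matching Packet Generator for Wearable ECG Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-bandwidth single-lead ECG telemetry built around a
    matrix pattern-matching heartbeat classifier. Detects R-peaks with a
    filter/derivative/adaptive-threshold chain, trains a time-by-amplitude
    occupancy matrix of normal PQRST morphology, scores each beat with the
    ratePM matched-cell statistic, and transmits full waveform data only for
    beats classified abnormal. Includes a bit-exact variable-size packet
    codec, receiver-side signal reconstruction, evaluation metrics
    (compression ratio, correlation, RMSE, detection accuracy), a seeded
    synthetic ECG generator with ground-truth beat annotations, and readers
    for WFDB and plain CSV signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    zoo,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
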