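Package: adascreen
Title: Amplitude Deviation Screening of Stage-Labelled Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens log-scale gene expression matrices with disease-stage
    labels (control, incipient, moderate, severe) for candidate genes whose
    expression departs from the cohort baseline. Implements the amplitude
    deviation algorithm: per-sample column centering, per-stage overall
    deviations, signed and absolute deviation amplitudes relative to the
    control stage, 3-sigma outlier thresholds, and monotone-trend selection
    criteria. Ships readers for plain TSV matrices and GEO series-matrix
    files, distribution diagnostics for the amplitude statistics, a
    synthetic-data simulator with planted monotone genes for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
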