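Package: cuffcomfort
Title: Cuff-Pressure Discomfort Analysis from Electrodermal Activity,
    Tissue Oxygen Saturation and Visual Analog Scale Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pressure-induced discomfort at the binding
    parts of wearable and rehabilitation devices. Simulates seeded cohorts of
    pneumatic-cuff experiments (skin conductance at 1 kHz, near-infrared
    spectroscopy at 5 Hz, visual analog scale ratings with a 60 kPa anchor),
    decomposes electrodermal activity into tonic and phasic components with a
    zero-phase 0.05 Hz high-pass filter, detects skin conductance responses,
    computes tissue oxygen saturation and its 30-s block-averaged decrease
    under occlusion, normalizes VAS ratings against the anchor, and runs the
    within-subject inference stage (repeated-measures ANOVA with
    Greenhouse-Geisser correction and Mauchly's sphericity test, post hoc
    paired t-tests, and Pearson correlations against normalized VAS),
    emitting summary tables and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
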