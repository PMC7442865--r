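Package: tonocal
Title: Acoustic Self-Tonometer Signal Evaluation and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evaluation pipeline for acoustic tonometry: a pressure chamber
    placed on the orbit couples the eye, the enclosed air and a loudspeaker,
    and the damping and frequency of the excited oscillation carry
    information about intraocular pressure (IOP).  The package simulates
    virtual cohorts and raw two-channel recordings (displacement and chamber
    pressure), extracts per-pulse damping and frequency by zero-crossing and
    log-envelope analysis, applies signal-validity gating (zero-crossing
    count, 350-570 Hz band, minimum valid pulses), calibrates IOP against a
    reference tonometer with an ensemble of small two-hidden-layer
    feedforward networks selected over repeated training trials, and
    quantifies agreement by regression and Bland-Altman expanded
    measurement uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
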