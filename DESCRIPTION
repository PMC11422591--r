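Package: photolick
Title: Fiber-Photometry Dopamine Signal Analysis for Lick-Based Reward Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-wavelength fiber-photometry recordings
    of a fluorescent dopamine sensor during head-fixed licking behavior.
    Provides lock-in demodulation of carrier-modulated detector voltage,
    isosbestic (405 nm) correction and dF/F0 computation, per-mouse
    z-normalization, lick detection from piezo voltage, trial parsing for
    free-licking, whisker-detection, delayed-reward and reward-omission task
    structures, signal-detection metrics (loglinear-corrected d-prime),
    event-aligned window quantification, within-session satiety analyses,
    and across-trial learning-dynamics statistics. A synthetic session
    generator with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    arrow,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
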