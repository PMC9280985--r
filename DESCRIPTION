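Package: neckcore
Title: Cervical Muscle EMG and Locomotor Kinetics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for surface electromyography (EMG) and
    kinetics of running and countermovement jumping, built around studies of
    cervical "core stabilization". Provides stride- and jump-locked EMG
    ensemble averaging with maximum-voluntary-contraction (MVC)
    normalization, accelerometer processing (gravity calibration, foot-strike
    detection, flight-phase baselining, per-step statistics, tilt
    correction), force-plate countermovement-jump kinetics via the
    impulse-momentum method, per-subject manipulation/control activation
    ratios with paired one-tailed Wilcoxon signed-rank tests under
    Holm-Bonferroni sequential correction, and an exponential fit of
    integrated EMG against jump impulse. A synthetic multi-subject study
    generator with known ground truth (activation envelopes, effect
    multipliers, stride mechanics, jump impulses) makes every stage of the
    pipeline verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
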