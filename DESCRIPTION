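Package: corrcomp
Title: Single-Trial Correlated Component Analysis for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatial filters whose projected single-trial EEG band
    power maximally correlates with a continuous behavioral variable such as
    reaction time. Provides a regularized closed-form solver with temporal
    augmentation, Morlet time-frequency decomposition and band-power dataset
    construction, single-trial correlated components, component correlation
    traces, forward-model (activation pattern) recovery, a sliding-window scan
    with cross-validated performance, permutation-based significance and FDR
    control, minimal deterministic preprocessing (filtering, epoching,
    baseline removal, average re-reference, EDF input/output), and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
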