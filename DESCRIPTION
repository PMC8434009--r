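Package: erpbci
Title: Simulation and Decoding of P300 Oddball Brain-Computer Interface Selections
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Offline toolkit for seven-button P300 oddball brain-computer
    interface (BCI) experiments of the kind used for hands-free drone
    control in virtual- and augmented-reality headsets. Provides a seeded
    synthetic EEG simulator (flash schedules, template P300 responses,
    realistic noise and artifacts), the standard single-trial decoding
    pipeline (ear re-referencing, 0.1-30 Hz Butterworth filtering,
    epoching, baseline correction, consecutive-epoch averaging,
    decimation), shrinkage-regularized linear discriminant classification
    with summed-score button selection, amplitude-threshold quality
    control at epoch/selection/subject level, P300 peak latency and
    amplitude measurement, and the nonparametric statistics (exact
    Wilcoxon tests with tie handling, Kolmogorov-Smirnov normality
    screening, Benjamini-Hochberg correction) used to compare recording
    environments. Ships transcriptions of published per-subject
    performance tables and reproduces their summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
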