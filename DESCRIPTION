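Package: ernsim
Title: Simulation and ERP Analysis of Error Prediction in a Virtual Throwing Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for studying error-related negativity (Ne/ERN)
    in a semi-virtual skittles throwing task. Provides a deterministic physics
    and scoring engine for the task (elliptic ball flight around a central
    post), a synthetic cohort generator producing behavioral trial tables and
    continuous multichannel EEG with injected error-related components,
    BrainVision-style EEG input/output, signal conditioning (zero-phase
    Butterworth band-pass, averaged-mastoids re-referencing, ocular artifact
    removal by regression or Infomax independent component analysis, epoch
    extraction, whole-segment baseline correction, artifact rejection), the
    behavioral hit/error categorization with two-level participant exclusion,
    and the event-related potential difference-wave statistics (data-driven
    window detection, mean amplitudes, one-sample t-tests, performance
    correlations), tied together by a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
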