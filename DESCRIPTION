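Package: earsleep
Title: Automatic Sleep Staging from Ear-EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic sleep staging from in-ear EEG. Provides
    EDF reading and writing, rejection of deteriorated ear electrodes by a
    median pairwise band-power rule, construction of left-minus-right and
    within-ear analysis derivations, extraction of 99 spectral, temporal,
    EMG-proxy, EOG-proxy and sleep-event features per 30-second epoch, a
    bagged decision-tree stage classifier, contiguity-aware cross-validation
    (leave-one-subject-out, pooled and per-subject schemes), hypnogram
    agreement metrics (Cohen's kappa, confusion matrices, per-stage
    sensitivity and specificity at 5-, 3- and 2-stage resolution), and a
    seeded synthetic sleep-EEG generator with stage-dependent spectra for
    end-to-end testing without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    randomForest,
    SummarizedExperiment,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
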