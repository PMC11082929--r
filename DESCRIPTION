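Package: speechtrf
Title: Subcortical and Cortical Temporal Response Functions from
    Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates auditory temporal response functions (TRFs) at
    subcortical and cortical levels from the same continuous-speech EEG
    recording using time-lagged ridge regression with Laplacian
    regularization. Provides the two EEG conditioning chains needed for
    dual-level analysis (a causal wide-band chain for brainstem-latency
    responses and a zero-phase low-frequency chain for cortical
    responses), evoked-response averaging, windowed peak extraction
    (wave V, N1, P2) with cluster-based electrode permutation tests, and
    a statistics layer combining nonparametric group comparisons,
    Bayesian rank tests with Bayes factors and region-of-practical-
    equivalence summaries, and frequentist plus Bayesian logistic
    regression. A synthetic-data module simulates multi-channel EEG
    cohorts with known ground-truth response kernels so the whole
    pipeline can be exercised and validated without access to any
    recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
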