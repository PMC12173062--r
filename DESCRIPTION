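Package: broilervoc
Title: Broiler Vocalization Monitoring from Continuous Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for acoustic monitoring of broiler chicken
    vocalizations: seeded synthesis of call soundscapes with exact ground
    truth, acoustic preprocessing (resampling, high-pass filtering, spectral
    gating, log-mel features), a fully-convolutional neural recognizer
    emitting normalized class probabilities every 240 ms plus an age
    estimate, threshold-based quantification of per-minute vocalization
    durations, and mixed-effects statistics of diurnal, age and treatment
    effects with Tukey HSD post-hoc comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
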