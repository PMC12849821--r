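Package: serialdep
Title: Serial Dependence Modelling, Response-Autocorrelation Audits, and
    n-Back Reanalysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying serial dependence in continuous
    reproduction tasks with derivative-of-Gaussian (DoG) tuning curves.
    Implements generative trial-series models with stimulus or response
    feedback, their impulse responses, n-back DoG fits by profiled
    nonlinear least squares with Wald confidence intervals, a
    residualization correction that removes the 1-back response effect
    before testing more remote stimulus effects, Monte-Carlo audits of
    spurious n-back associations, a preprocessing pipeline for empirical
    orientation-reproduction data (polynomial debiasing, outlier removal
    with followers, block-start trimming), nonlinear mixed-effects DoG
    models with per-subject random amplitude and intercept, a
    within-subject permutation test of the correction, and a synthetic
    multi-subject cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
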