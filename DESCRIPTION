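Package: awedyn
Title: Time-Course Modelling of Bodily Responses During Awe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics of psychophysiological
    signals recorded while participants watch emotion-inducing videos.
    Provides skin conductance response (SCR) event detection and feature
    summaries, pupillometry preprocessing (de-blinking, interpolation,
    smoothing, missingness exclusion), a Bayesian smoothed-trend state-space
    model with second-order differencing whose trend-disturbance standard
    deviation quantifies per-series fluctuation, hierarchical Bayesian mean
    comparisons with contrast coding and multiple imputation by chained
    equations, and a synthetic physiological-data generator with recorded
    ground truth so the full pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
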