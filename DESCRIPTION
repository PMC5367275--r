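Package: chronotrack
Title: Chronotypes and Behavioural Repeatability from Acoustic Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decodes daily active/resting behavioural states from acoustic
    detection time series of free-ranging fish with two-state Poisson hidden
    Markov models, derives circadian traits (awakening time relative to
    sunrise, rest onset relative to sunset, rest duration) and daily travelled
    distance from an Ornstein-Uhlenbeck home-range movement model with Kalman
    smoothing, and quantifies chronotypes by decomposing trait variance into
    between- and within-individual components with Bayesian random-intercept
    mixed models (adjusted repeatability, DIC-based model reduction and
    significance, Durbin-Watson autocorrelation checks) and bivariate models
    for between-individual versus residual trait correlations. Includes a
    synthetic-telemetry generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmtest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'chronotrack-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'repeatability.R'
    'bivariate.R'
    'hmm.R'
    'io.R'
    'movement.R'
    'traits.R'
    'synthetic.R'
    'pipeline.R'
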