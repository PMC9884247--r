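Package: pursuitmvpa
Title: Reliability-Weighted Cue Integration Analysis for Smooth Pursuit and Multichannel Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reliability-weighted (Bayesian) integration of
    a motion cue and a pursuit target in smooth pursuit eye movements and in
    simultaneously recorded multichannel neural epochs. Provides a synthetic
    generator of eye traces and forward-modelled epochs, saccade screening and
    rotated-trace distance statistics, sensory and motor feature traces
    (retinal velocity error and its time integral), cross-validated
    Mahalanobis dissimilarity time courses with trial-count matching and
    channel-subset rules, a time-shifted linear model relating neural
    dissimilarity to sensory and motor dissimilarities, and cluster-based
    permutation inference for time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
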