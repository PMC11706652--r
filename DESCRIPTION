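Package: phenometa
Title: Meta-Analysis of Temperature and Year Effects on Fish Reproductive Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fixed-effect meta-analysis pipeline for synthesizing correlations
    between annual predictors (temperature indices or calendar year) and the
    reproductive timing of temperate freshwater fishes. Provides Fisher's Z
    transformation with inverse-variance weighting and pooling, construction of
    inclusive and conservative (one effect per species per study) analysis
    datasets, Egger-type regression diagnostics of funnel-plot asymmetry,
    analysis of covariance of interannual spawning-date ranges on study
    duration and season with estimated marginal means, and a seeded synthetic
    study generator that emulates the statistical structure of published
    phenology time series so that every stage of the pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
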