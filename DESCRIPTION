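Package: navlearn
Title: Learning-Curve Modelling and Brain-Behaviour Correlation Analysis
    for Virtual Water-Maze Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies individual spatial-learning rate from trial latencies
    in virtual Morris Water Maze tasks and relates it to white-matter tract
    microstructure.  Provides power-law learning-curve fits with a data-driven
    quadratic-trough cut-off, permutation-based screening of participants who
    show no behavioural evidence of learning, median-absolute-deviation
    outlier filtering, and a directional inferential suite: one-sided Pearson
    and Spearman correlations, Steiger Z tests for dependent overlapping
    correlations, default Bayes factors for correlations under a
    stretched-beta prior with Bayesian credible intervals, JZS partial
    correlations, and bootstrap comparison of dependent Spearman
    correlations.  A synthetic cohort generator (latency series, correlated
    tract metrics, covariates, and an arena navigation agent) makes every
    analysis stage testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
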