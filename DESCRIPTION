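Package: ppdesigns
Title: Predictive Probability Monitoring for Randomized Biomarker-Guided
    Phase II Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and calibration of randomized phase II oncology trials
    with biomarker subgroups and Bayesian futility monitoring. Implements
    two-sample beta-binomial posterior predictive probability monitoring,
    three randomized trial topologies (a pooled control arm shared across
    biomarker-specific treatment subgroups, a stratified control arm within
    each subgroup, and a two-stage enrichment design that selects the most
    promising subgroup), simulation-based estimation of type I error, power
    and expected sample size over a grid of posterior and predictive
    thresholds, optimal-efficiency design selection, and generation of
    decision-rule tables for trial conduct.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
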