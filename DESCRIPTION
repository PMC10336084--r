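Package: sfcoupling
Title: Regional Structure-Function Coupling in Longitudinal Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify and model the developmental coupling between
    structural and functional brain connectivity. Builds weighted connectomes
    from ROI time series and streamline counts, applies consistency-based
    thresholding of structural edges (75th percentile of the edge-weight
    coefficient of variation), computes regional structure-function coupling
    as the Spearman rank correlation between each region's non-zero structural
    and functional connectivity profiles, and models regional developmental
    trajectories with penalized-spline generalized additive mixed models
    (subject random intercepts, maximum-likelihood fitting, nested
    likelihood-ratio/AIC model ladder, Benjamini-Hochberg FDR across regions).
    Includes a seeded synthetic-cohort generator that emulates a longitudinal
    case-control neuroimaging study with planted coupling trajectories, so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
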