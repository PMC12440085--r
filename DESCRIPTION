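Package: fccontrast
Title: Edge-Wise Contrast Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for group-level analysis of resting-state functional
    connectivity from parcellated BOLD time series. Builds per-subject
    Fisher z-transformed Pearson correlation (connectivity) matrices,
    computes edge-wise cross-sectional group contrasts and
    placebo-subtracted (difference-in-differences) longitudinal treatment
    contrasts with Benjamini-Hochberg false-discovery-rate control,
    classifies significant edges directionally against a noise band of
    effectively-zero connectivity, and aggregates classified edges into
    hemisphere, lobe and functional-network pair tables and region hub
    summaries for chord-diagram export. A companion regional-statistics
    layer covers standardized-uptake-value-ratio and intracranial-volume
    normalized comparisons, per-region marker regressions with
    within-lobe FDR, and two-arm pre/post interaction tests. A synthetic
    cohort generator simulates stationary multivariate Gaussian ROI time
    series with designed group correlation structure and known injected
    edge effects so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
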