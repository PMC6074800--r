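Package: pcmc
Title: Post-Conflict/Matched-Control Analysis of Behavioural Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative ethology toolkit for post-conflict behaviour in
    group-living animals. Implements the post-conflict/matched-control
    (PC/MC) observation method with a deterministic matched-control
    selection ladder, attracted/dispersed/neutral pair classification and
    per-victim reconciliation tests; the time-rule method (latency
    histograms, cumulative first-contact curves, interval-wise association
    tests and critical-interval determination); third-party-intervention
    and affiliative contact-typology summaries; exact small-sample
    statistics (enumeration-based Wilcoxon signed-rank, Fisher's exact
    tests with conditional-MLE odds ratios, two-sample Kolmogorov-Smirnov,
    Cohen's kappa); and a seeded generator of synthetic behavioural coding
    sheets with post-conflict affiliation effects for end-to-end pipeline
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
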