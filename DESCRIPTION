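Package: tidysig
Title: Single-Sample Signature Scores with Resampling-Based Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes molecular signatures (gene sets with optional
    per-feature weights) into single per-sample scores over an expression
    matrix, using a battery of scoring metrics: robust location and
    dispersion summaries (trimean, midhinge, interquartile mean, MAD and
    friends), combined z-scores, the first principal component, PLAGE,
    single-sample GSEA and GSVA-style enrichment statistics. Scores compose
    with built-in data transformations (step, quantile normalization,
    z-standardization), and their robustness and significance are assessed
    through resampling-based empirical null distributions (data resampling
    with or without replacement, or random same-size signatures), yielding
    achieved significance levels, standard errors and percentile bootstrap
    confidence intervals. All results are tidy tibbles; tabular summaries
    back boxplot, correlation-heatmap, score-heatmap and null-histogram
    displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
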