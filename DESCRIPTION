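Package: intensityLM
Title: Intensity- and Ratio-Based Genewise Linear Models for Dual-Color
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genewise ANOVA of two-channel (Cy3/Cy5) gene-expression
    microarray data either on within-array log-ratios (linear model with a
    per-gene array effect) or directly on single-channel log2 intensities
    (no array effect).  Provides quantile normalization and mean-intensity
    filtering of pooled channels, BIC model selection between the two
    analyses per probe, technical-replicate reproducibility metrics
    (Spearman rho of p-values, ranked-bin and top-k overlap curves,
    M-value correlations), in-silico ratio reconstruction, analytic power
    comparison of paired versus two-sample analyses via the non-central t
    distribution, and a variance-component simulator of common-reference,
    dye-swap, factorial and interwoven-loop hybridization designs with
    ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
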