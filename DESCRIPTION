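Package: t2esig
Title: Rank-Based Gene-Pair Signatures for TMPRSS2-ERG Fusion Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and applies qualitative, rank-based gene-pair signatures
    that call TMPRSS2-ERG (T2E) fusion status from bulk or single-cell
    transcriptomes. Reference genes are selected by fusing five expression
    variability metrics (ANOVA F-statistic, Shannon entropy, coefficient of
    variation, outlier sum, median absolute deviation) by rank aggregation;
    anchored ERG-reference pairs are screened by a reverse-degree statistic on
    within-sample ranks and by the harmonic mean of sensitivity and
    specificity; a majority-vote signature is assembled by seeded greedy
    forward selection. Because classification depends only on within-sample
    relative expression orderings, calls are invariant to any per-sample
    monotone transform and hence portable across platforms without
    renormalization. Single-cell samples are called through repeated random
    pseudobulk construction and an exact binomial vote test. Includes a
    synthetic-data generator with planted rank-reversal structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
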