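Package: cernoscore
Title: Per-Cell Gene-Signature Scoring and CERNO Enrichment for Two-Condition Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores gene signatures in individual cells of droplet single-cell
    RNA-seq experiments by a rank-index method and an expression-sum method,
    combines them into a scaled average, and tests per-cell signature
    enrichment with the CERNO statistic (Fisher's combination of log relative
    ranks, chi-square distributed under the null). Per-cell p-values are
    FDR-corrected within each experimental condition and conditions are
    compared by Fisher's exact test on the counts of significantly enriched
    cells, and by a two-sided Wilcoxon rank-sum test on the scores themselves.
    Includes the surrounding droplet workflow steps (cell and gene quality
    filters, log-normalization, per-gene scaling, equal-size downsampling,
    one-vs-rest Wilcoxon marker detection, cluster-composition shift tests)
    and a negative-binomial simulator of two-condition, multi-cluster count
    matrices with planted signature effects for validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
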