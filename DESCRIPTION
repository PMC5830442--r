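Package: neighborvote
Title: Cross-Dataset Replicability of Single-Cell Transcriptomic Cell Types by Neighbor Voting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well cell types defined from single-cell RNA-seq
    replicate across independent datasets. Builds a rank-standardized Spearman
    cell-cell similarity network over a gene set, scores cell-type membership
    by degree-normalized neighbor voting under leave-one-dataset-out
    cross-validation, and reports performance as analytically computed AUROCs.
    Includes gene-set selection heuristics (GMT parsing with size filters,
    size-matched random sets, coefficient-of-variation centile sets, and a
    decile-binned highly-variable-gene procedure), reciprocal-best-hit matching
    of cluster labels across studies, an empirical model of cell-type rarity
    and transcriptional subtlety, meta-analytic marker discovery combining
    per-dataset one-sided Wilcoxon tests with Fisher's method, and a synthetic
    multi-study data generator for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
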