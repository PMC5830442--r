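---
title: "Cross-dataset replicability of cell types by neighbor voting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset replicability of cell types by neighbor voting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neighborvote)
```

## The model and its assumptions

`neighborvote` treats cell-type replicability as a supervised prediction
problem. The premise: if a cell type has a transcriptional identity that is
more than a clustering artifact, then labels learned in one laboratory's
data should let us recognize cells of the same type in another laboratory's
data. The procedure makes three assumptions worth stating explicitly:

* **Identity is encoded in relative expression.** All similarity is
  Spearman correlation over a gene set, so only the within-cell ranking of
  genes matters. This buys invariance to depth, scaling and any monotone
  normalization, at the price of ignoring magnitude information.
* **All cells are neighbors.** Unlike k-nearest-neighbor classifiers there
  is no truncation; every cell votes with a weight, and a cell's node
  degree (the sum of its weights, self-edge included) is the null predictor
  that corrects for hubness.
* **Evaluation must not mix laboratories.** In leave-one-dataset-out
  cross-validation the held-out study contributes no labels, and the AUROC
  ranks only the held-out study's cells against each other. A batch effect
  that shifts a whole study therefore cannot inflate the score; only
  structure that replicates across studies can.

Scores are analytic AUROCs computed from rank sums,
`sum(Ranks_pos)/(N * N_neg) - (N + 1)/(2 * N_neg)`, identical to the
normalized Mann–Whitney U statistic; the equivalence against a brute-force
pairwise oracle (ties counting one half) is exercised to 1e-12 in the test
suite. A fold with no positives or no negatives among the test study's
labeled cells is undefined and excluded from the fold mean rather than
imputed.

## Parameters that matter

| parameter | default | units / scale | why this default |
|---|---|---|---|
| `min_genes` (cell QC) | 1000 | detected genes per cell | standard floor for single-cell libraries; strictly-fewer-than semantics |
| gene-set size filter | 20–1000 | genes, after universe intersection | below 20 correlations are unstable; above 1000 sets lose specificity |
| HVG `n_expr_bins` | 10 | expression deciles | controls the mean–variance trend before picking variable genes |
| HVG `top_fraction` | 0.25 | fraction per bin | quarter of each bin, `ceiling`ed so small bins keep a gene |
| match `threshold` | 0.95 | AUROC | extreme-confidence cutoff for calling two subtype labels replicates |
| `max_cells` | 50000 | cells | the network is dense O(cells²); the API refuses larger inputs rather than thrash |
| DE `fdr_max` / `min_log2fc` | 0.001 / 2 | meta FDR, per-dataset log2 FC | stringent marker definition; FC must hold in *every* contributing dataset |
| model `n_reps` | 100 | replicates per grid point | stabilizes the replicate mean to ~±0.01 AUROC |

## Numerical and design choices

Points where the design was genuinely open, and what this package does:

* **Rank standardization granularity.** Network weights are ranked jointly
  over the entire matrix (not per row) and divided by the maximum rank.
  Joint ranking is the only choice that keeps the matrix exactly symmetric,
  and average ranks for ties keep the transform deterministic. Self-edges
  participate in the ranking, so diagonal entries sit at the top; they also
  contribute to the degree denominator, but a hidden test cell's own label
  is 0, so it can never vote for itself.
* **Zero-variance cells.** A cell with constant expression across a gene
  set has no defined correlation; its off-diagonal entries become 0 with a
  warning. This keeps the network total and finite instead of propagating
  NaN.
* **HVG variability statistic.** "Most variable within an expression bin"
  is implemented as within-bin variance (CV available as an option):
  binning by mean expression already controls the mean–variance trend, so
  plain variance is the simplest faithful statistic. Bin-edge and
  within-bin ties break lexicographically by gene id for determinism. The
  most highly expressed bin is excluded entirely.
* **Combining HVG lists.** Intersection by default; majority rule (strictly
  more than half of studies) as the documented fallback. With only two or
  three studies the intersection can collapse to a handful of genes — and a
  tiny set composed mostly of one type's markers can be degenerate, because
  out-group cells have near-zero variance across it. The error message
  recommends the majority rule for exactly this situation.
* **Replicate grouping rule.** Candidate edges are the union of reciprocal
  best hits and cross-study pairs scoring at or above the threshold; a
  `strict` flag switches to the conjunctive reading. Groups are connected
  components of the candidate graph — the minimal closure rule consistent
  with three-study groups — with ties and chains flagged in the edge table
  rather than silently resolved. Within-study entries of the pairwise
  matrix come from seeded 2-fold cross-validation inside the study and are
  flagged as such; the diagonal is defined as 1.
* **Rarity/subtlety model bookkeeping.** Incidence uses half-up rounding of
  `r * n`; each positive is paired with a distinct held-out negative donor
  (a fixed random bijection per replicate) and strict partitioning of
  donors from analyzed cells is asserted every replicate. The swapped gene
  subset is drawn once per replicate from the full universe — subtlety is a
  property of the transcriptome, not of the scoring set — and shared across
  datasets within the replicate (the alternative, redrawing per dataset,
  would blur the nominal subtlety level). Replicate seeds derive from the
  master seed by a counter so any single replicate reproduces in isolation.
* **Meta-DE conventions.** One-sided Wilcoxon with the "greater in the
  target type" alternative (marker discovery implies enrichment); exact
  enumeration at combined n ≤ 20 without ties, normal approximation with
  tie and continuity correction otherwise. Fold changes use means with a
  pseudocount of 1 on the supplied expression scale, which keeps
  dropout-heavy genes finite; BH is applied across genes within each cell
  type (one family per type). Zero p-values are clamped to the smallest
  positive double before Fisher combination, with a warning.
* **Merging.** Cell ids are namespaced `study|cell` (barcodes recur across
  laboratories); duplicate gene rows are averaged before merging; genes
  missing from a study are zero-filled; the gene universe is an explicit
  argument defaulting to the union of study genes, since platform-specific
  probe intersections are external data. The coverage filter runs on raw
  stored values, before any transformation.

## What the synthetic generator emulates — and what it does not

`generate_studies()` draws per-gene baseline means from a lognormal
(heavy-tailed, positive), shifts each type's disjoint marker block by
`2^effect_size`, multiplies every gene by a study-specific lognormal batch
factor (sd `batch_sd`), samples negative-binomial counts (variance
`mu + dispersion * mu²`) and applies independent dropout. That reproduces
the features the method must cope with: laboratory-specific multiplicative
bias, overdispersed counts, sparsity, and types defined by a minority of
genes. It does **not** emulate library-size gradients within a study,
correlated gene modules beyond the marker blocks, doublets, or
ambient-RNA contamination — so a passing calibration here shows the
procedure behaves correctly under its stated model, not that any particular
real pair of datasets will replicate. `generate_disjoint_studies()` is the
idealized positive control (disjoint expression support, hence AUROC 1),
and `shuffle_labels()` the matched negative control (labels independent of
expression, hence AUROC 0.5).

## Problem sizes used in the checks

The calibration suite runs at deliberately modest sizes, chosen so each
check isolates one property rather than for realism: null calibration uses
3 studies × 2 types × 30–50 cells per type × 500 genes with 100 random
100-gene sets; the rarity/subtlety sweeps use 50–100 analyzed cells per
dataset with 100 replicates per grid point; matching recovery uses 20
seeded replicates of a 3-study × 4-type design with batch sd 0.7; the
meta-DE null uses 200 replicates of 100 exchangeable genes. At these sizes
the chance-level bands (0.45–0.55) and the monotonicity tolerance (0.02
between adjacent subtlety levels) are comfortably resolved by the
replicate counts.

## Known limitations

* The dense cell–cell network is quadratic in cells; above the configured
  ceiling the API refuses rather than approximates. No low-rank or sparse
  variant is provided.
* Scores depend on the out-group: an AUROC is only as meaningful as the
  negatives it ranks against, and the closest out-group is the most
  informative comparison.
* Cluster labels are taken as given. When studies cluster to different
  depths, one broad label can legitimately match several finer ones; the
  grouping rule surfaces these as multi-member components rather than
  adjudicating them.
* Replicability is evidence of a shared transcriptional signature, not of
  biological cell-type status; orthogonal (non-transcriptomic) evidence is
  outside the package's scope.
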