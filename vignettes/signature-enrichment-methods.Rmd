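---
title: "Per-cell signature scoring and CERNO enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell signature scoring and CERNO enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernoscore)
```

# The scientific question

In droplet single-cell RNA-seq experiments comparing two biological
conditions — here labelled `shSELP` and `shNC` after the SELP-knockdown
versus control glioma model this workflow was designed around — a common
question is whether a *gene signature* (a curated list of genes, optionally
split into up- and down-regulated members) is more active in the cells of
one condition. Cluster-level differential expression answers a different
question; signature activity must be quantified *per cell* and then compared
across conditions. This package implements three complementary layers:

1. **Per-cell scores** — a rank-index score and an expression-sum score,
   combined into a scaled average, which quantify signature activity on a
   relative scale suitable for visualization and for score-level tests.
2. **A per-cell enrichment test** — the CERNO statistic, Fisher's
   combination of the log relative ranks of the signature genes, which
   attaches a p-value to every single cell.
3. **Condition-level aggregation** — per-condition FDR correction of the
   per-cell p-values followed by Fisher's exact test on the counts of
   significantly enriched cells, plus a two-sided Wilcoxon rank-sum test
   directly on the scores.

# Models and procedures

## Quality control and normalization

Cells are removed if strictly more than 10% of their raw counts come from
mitochondrial genes (IDs prefixed `mt-`, the mouse convention) or if they
detect strictly fewer than 500 genes; both thresholds are read literally, so
a cell at exactly 10% or exactly 500 genes is retained. The mitochondrial
share is computed on raw counts before any other filtering, so QC never
depends on normalization. After cell QC, genes detected in strictly more
than 3 cells are kept. The order matters — gene detection counts change when
cells are removed — and the workflow fixes the cells-first order.

Normalization divides each count by its cell's total, multiplies by a scale
factor *s* and applies `log1p`:

$$x_{gc} = \log\!\big(1 + s \cdot n_{gc} / \textstyle\sum_g n_{gc}\big),
\qquad s = 10{,}000.$$

*s* is configurable; 10,000 is the long-standing default of the standard
droplet toolchains. The invariant `sum(expm1(x)) == s` per cell is tested to
1e-6 relative. Per-gene z-scoring (mean 0, sample standard deviation 1 with
the *n*−1 denominator, constant genes mapped to zero, values clipped at
±10) removes the bias toward highly expressed genes before rank-based
scoring. Equal-size comparison of conditions uses seeded uniform
downsampling without replacement.

## The two scores and their combination

For the **rank-index score**, each cell's z-scored expression vector is
ranked ascending (rank 1 = lowest; ties get average ranks) and the ranks of
the signature members are summed; for bidirectional signatures the
down-member rank sum is subtracted from the up-member rank sum. Ascending
ranks make larger scores mean "signature more expressed", which is the
orientation used when projecting scores onto embeddings. Average ranks keep
the score independent of gene order in zero-inflated, tie-heavy matrices.

The **expression-sum score** sums the z-scored expression of the up members
and subtracts the down-member sum. The up-minus-down orientation is a
deliberate reading: the alternative (down minus up) would anti-correlate
the two scores and make their average meaningless; the `direction` argument
exposes the reversed convention.

The **combined score** z-scores both vectors across cells and averages
them. It has mean 0 by construction; the 10th-percentile high-score mask
(strictly above the linear-interpolation percentile) reproduces the "highly
scored cells" selection used for contour overlays.

## The per-cell CERNO statistic

For each cell, genes are ranked by log-normalized expression *descending*
(rank 1 = highest, average ranks for ties) and

$$F \;=\; -2 \sum_{i=1}^{N} \ln\!\frac{r_i}{N_{tot}}, \qquad
F \sim \chi^2_{2N} \text{ under the null},$$

where \(r_i\) is the rank of signature gene *i*, *N* the resolved signature
size and \(N_{tot}\) the total gene count. Descending ranks are the only
orientation under which high expression of signature genes yields small
relative ranks and hence large *F*; ascending ranks would invert the test.
The per-cell p-value is the upper-tail chi-square probability at *F*. For
bidirectional signatures the members are pooled — the statistic is unsigned,
so a strong planted *down* program partially cancels a strong *up* program;
score-level tests keep the sign information.

Per-cell p-values are then Benjamini–Hochberg corrected *within each
condition* ("FDR" is read as BH; no specific flavor is mandated by the
procedure's description), a cell is called enriched when `q < 0.05` (a
decision, exposed as `q_threshold`), and the 2×2 table of enriched/not by
condition is evaluated with Fisher's exact test — two-sided by default, with
the one-sided variants exposed. The odds ratio reported is the raw
cross-product \(ad/bc\); zero cells propagate `Inf`/`NaN` rather than being
continuity-corrected, since the exact p-value, not the odds ratio, carries
the inference.

## Calibration: what holds where

The chi-square law for *F* is the sampling distribution under the
statistic's own null — signature ranks uniform, i.e. exchangeable genes with
a continuous expression distribution. Two departures matter in practice,
and both are characterized by tests:

* **Count ties.** Sparse integer counts tie large rank blocks (zeros alone
  are ~40% of genes at typical depth; counts of 1, 2, ... form further
  blocks). Tie-averaging raises the mean log relative rank (Jensen's
  inequality), so *F* sits *below* its nominal mean and the per-cell
  p-values are conservative — measured mean *F* ≈ 95 against a nominal 100
  at *N* = 50. The direction of the bias is safe: it cannot manufacture
  enriched cells.
* **Baseline heterogeneity.** For a *fixed* signature, per-cell ranks are
  not exchangeable across genes: a signature whose members have high (or
  low) baseline expression concentrates *F* around the corresponding
  quantiles in *every* cell. Per-cell p-values are therefore not uniform
  across cells of real data even without any condition effect. The
  cross-condition design absorbs this: both conditions share the same
  baseline bias, so the Fisher comparison of enriched-cell counts remains
  calibrated — type-I error of the full chain is ≤ 6% over 200 null
  simulations at α = 0.05, and is in fact strongly conservative.

Also worth knowing: with discrete ranks
\(E[F] = N\,(2 - \ln(2\pi N_{tot})/N_{tot} + O(N_{tot}^{-1}))\), so the
"mean *F* = 2*N*" property is asymptotic in the total gene count (−3.2% at
\(N_{tot}=100\), −0.2% at 2,000). Unbiasedness checks therefore run at the
study-scale gene count.

The per-cell FDR dichotomization is stringent by design: in the worked
analysis a planted one-unit log-fold program flags most target-condition
cells, while a 0.5 log-fold program flags almost none — yet both are
overwhelmingly detected by the score-level Wilcoxon test. When per-cell
calls are sparse, the condition-level tests carry the inference.

## Markers and composition

One-vs-rest marker detection pre-filters genes before testing: detection
(nonzero raw count) in ≥ 0.25 of cells on at least one side, and
\(|\mathrm{logFC}| \ge 0.25\) where
\(\mathrm{logFC} = \ln(\overline{e^{x}-1}_{in}+1) -
\ln(\overline{e^{x}-1}_{out}+1)\)
(the de-logged-mean formula of the standard toolchain; a plain
mean-difference variant is available). Surviving genes get two-sided
Wilcoxon rank-sum p-values and Bonferroni correction over the *total* gene
count — deliberately matching the reference toolchain's (conservative)
convention. Cluster-composition shifts between conditions use the same
shared Fisher routine per cluster with BH across clusters, a lighter
correction appropriate for a handful of clusters.

The rank-sum test is exact (full enumeration) when both groups have at most
8 observations and no ties, and otherwise uses the normal approximation with
tie and continuity corrections; the two agree within 0.01 at the crossover.

# The synthetic-data generator

`simulate_counts()` draws from a gamma–Poisson (negative binomial) law, the
standard overdispersed model for droplet counts: per-gene log-normal
baseline means (meanlog 0, sdlog 1), NB dispersion 0.4 (variance
\(\mu + 0.4\mu^2\)), per-cell log-normal size factors (sigma 0.35),
per-cluster multiplicative fold-changes of 2–4× on a random 5% of genes,
and planted per-condition log-fold shifts on signature members. Default
dimensions emulate the structure of the motivating experiment: two
conditions of 4,500 cells (the deposited groups held 4,654 and 5,708 cells,
downsampled to 4,580 each), 5,000 genes, six subpopulations. Thirteen
`mt-` genes take an expected share of each cell's counts equal to a
Beta(2.5, 50)-drawn mitochondrial fraction (mean ≈ 4.8%, ~5% of cells
beyond the 10% QC bound). Mitochondrial counts are conditionally Poisson
given the drawn fraction — the Beta fraction itself carries their
across-cell overdispersion, and layering NB noise on top would double-count
it and decouple the realized share from the drawn one.

What the generator does *not* emulate: doublets, ambient RNA, batch
effects, UMI-level errors, or gene–gene correlation beyond the cluster and
condition programs. Passing tests on this generator therefore demonstrate
the statistical machinery (calibration, power, direction recovery) under a
clean overdispersed model, not robustness to every artifact of real
droplet data.

Reproducibility contract: one integer seed feeds a single generator stream;
identical config + seed gives bit-identical matrices. Validation studies
(`signature_recovery_study()`) run at 2,000 genes and 500 cells per
condition with a 50-gene signature — sizes chosen to make repeated
simulation studies (hundreds of runs) routine on a laptop while keeping
per-cell library sizes (~3,000 counts) and detection fractions realistic.

# Numerical and degenerate-input conventions

* Zero counts map to exactly zero log-normalized expression, preserving
  sparsity; normalization refuses zero-total cells (they cannot be
  renormalized) and directs the user to cell QC.
* Scaling refuses single-cell input (sample sd undefined) and maps
  constant genes to all-zero rather than NaN.
* Signature members missing from the matrix are dropped with a warning
  (reducing *N* honestly); a fully unresolved signature is an error, never
  a silent zero score.
* Percentiles use linear interpolation (type-7 quantiles); the high-score
  mask is strict, so an all-equal score vector selects no cells.
* An all-equal score vector z-scores to zeros in the combined score.
* Fisher odds ratios with empty cells propagate IEEE `Inf`/`NaN`.
* Equal-size downsampling errors when a group is smaller than the request,
  naming the group.

# Known limitations

* The per-cell chi-square p-values are conservative on sparse counts (tie
  blocks) and non-uniform across cells under baseline heterogeneity;
  only the cross-condition comparison should be interpreted
  inferentially on real data.
* Pooling up- and down-members in the unsigned CERNO statistic weakens it
  for strongly bidirectional signatures; use the score-level tests when
  the direction split matters.
* Clustering and embedding are out of scope: cluster labels are an input
  (the simulator provides ground-truth labels; real data should bring its
  own), and no graph clustering or tSNE is performed here.
* Bonferroni over all genes for markers is intentionally conservative;
  interpret marker absence accordingly.
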