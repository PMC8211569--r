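---
title: "Screening cohorts for expression change and co-expression decoupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohorts for expression change and co-expression decoupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

`coexscreen` screens a panel of genes across K paired normal/cancer
expression cohorts for three kinds of signal: genes whose fold-change has
a consistent sign everywhere, genes differentially expressed everywhere,
and gene pairs whose Pearson correlation changes the same way everywhere.
This vignette documents the statistical choices behind each stage, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Input model

Each cohort is a nonnegative genes × samples matrix in FPKM-like units
with a sample-to-group map (`normal` / `cancer`). Cells may not be
missing: missingness is modelled at the cohort level — a gene absent from
one cohort's matrix simply contributes no record for that cohort, and the
screens ignore unavailable cohorts rather than imputing values. Gene
identity is the exact, case-sensitive symbol string; alias resolution is
out of scope. Cohorts are admitted only with at least `min_normal` (10)
normal and `min_cancer` (10) cancer samples, below which per-arm means and
correlations are too unstable to screen.

## Differential expression

Library sizes differ between samples, so each column is rescaled to the
median column sum of its matrix before anything else
(`normalize_library()`). The median of an even number of sums is defined
as the arithmetic mean of the two middle values — stated explicitly so the
scaling target is deterministic.

The per-gene effect size is the normalized log2 fold-change

$$\mathrm{log_2FC} = \log_2\frac{\bar{x}_{cancer}+\varepsilon}{\bar{x}_{normal}+\varepsilon},$$

positive when the gene is up in cancer. The pseudocount $\varepsilon$
(default $10^{-3}$, configurable) keeps the ratio defined at zero means;
it is chosen far below typical FPKM magnitudes so that fold-changes of
genuinely expressed genes are essentially untouched (a gene with mean 20
and a 128-fold drop still reports ≈ −7, which is the regime the screens
care about).

Significance uses a two-group likelihood-ratio test: H₀ one shared Poisson
mean versus H₁ one mean per group, evaluated on library-normalized values
rounded to integers, with Λ = 2(ℓ₁ − ℓ₀) referred to χ² with one degree of
freedom. The Poisson likelihood is the classical single-parameter reading
of a two-group expression LRT and is exactly testable against a
brute-force likelihood evaluation, which the test suite does. Two caveats
are deliberate: rounding normalized continuous values to pseudo-counts is
a modelling convenience, and real expression data are overdispersed
relative to Poisson, so raw p-values are anti-conservative. The screens
therefore never rely on the p-value alone — the fold-change cut-off
(|log2FC| ≥ 1 by default) carries the specificity, which is also why the
planted-data false-positive rate stays at zero in the recovery tests.
Degenerate input (both groups all zero) returns Λ = 0, p = 1, flagged.
P-values are screened raw per cohort at p < 0.05 by default;
Benjamini–Hochberg adjustment within cohort is available behind a flag.

When records carry no p-values at all — screening a printed fold-change
grid, which publishes no per-gene p — the p criterion is treated as
satisfied and the waiver is recorded on the result and echoed in the run
report, so grid-only screens remain possible without pretending a test
was run.

The trend screen uses strict sign: log2FC = 0 counts as neither direction,
so a flat gene can never be called consistent. Unavailable cohorts are
ignored; a gene available nowhere is excluded and reported.

## Correlation change

Per cohort and arm, Pearson correlations are computed (the `stats::cor`
path) on log₂(x+1)-transformed expression by default. FPKM is
heavy-tailed, and a monotone log transform keeps a handful of extreme
samples from dominating r; the transform can be set to `none` to match
analyses on the raw scale, and every run report states which was active.
Genes with zero variance in an arm yield undefined correlations, tracked
in an explicit mask rather than as numbers.

Classification of a pair's (r_normal, r_cancer) into the six transition
categories needs two thresholds the category names alone leave open:

* `sign_tau` (default 0.1): dead-zone half-width. r_normal within
  ±sign_tau is neither positive nor negative → category `undefined`.
* `delta_min` (default 0.1): minimum |r_normal − r_cancer| to call any
  change → otherwise `null_change`.

Both defaults are small symmetric values chosen once to make the six
categories well-defined; they are configuration knobs, and the
consistency-hit set can only shrink as either grows (a tested
monotonicity). Boundary conventions, stated once and enforced by an
exhaustive grid test: the dead zone and change gate are evaluated in that
order; `r_cancer` exactly at ±sign_tau counts as weakening, not as a sign
crossing; strengthening is strict (`r_cancer > r_normal` for a positive
start). Negating both correlations mirrors every category onto its
opposite-sign twin, a symmetry the tests assert on random input.

A pair is a cross-cohort hit when its category is identical, and one of
the six real categories, in every cohort where the pair is defined; with
`require_all` (the default) the pair must be defined in every cohort, the
strict intersection reading of "consistent across all cancer types". The
screen applies no significance filter to the correlation change itself —
none is implied by the category definitions — but a two-sample Fisher
z-test (`fisher_z_difference()`) is provided for users who want one.

## The synthetic generator

`generate_cohorts()` draws expression as exp(latent Gaussian). Background
genes are independent with identical distributions in both arms. A planted
DEG shifts the cancer-arm latent mean by log2FC·ln 2, which multiplies the
lognormal mean by exactly 2^log2FC. A planted pair draws its two latent
rows from a bivariate Gaussian with the per-arm target correlation — a
Gaussian copula, so the Pearson correlation of log-scale expression tracks
the target; no gene may join two pairs, keeping the planted covariance
block-diagonal and positive-definite by construction. One master seed
expands into per-cohort, per-arm substreams through a fixed counter
scheme, so adding a cohort never changes earlier cohorts' values.

Scale parameters: latent mean 3 and sd 0.5 on the natural-log scale,
i.e. median expression ≈ 20 with a lognormal coefficient of variation
≈ 0.53 — moderate biological spread for a bulk cohort. At these settings a
planted log2FC of −3 is recovered within ±0.3 at 50 samples per arm, and
a planted correlation within ±0.1 at 200 per arm, which the tests assert.

`paper_shaped_spec()` is the canned study-shaped configuration: 12 cohorts
with the published per-cohort sample counts (smallest: 11 normals), 127
genes, two planted DEGs at log2FC −3 and +2 (echoing the magnitudes of the
strongest reported markers), and five decoupling pairs, three weakening
from positive and two from negative. The correlation targets are ±0.95 in
normal falling to ±0.25 in cancer: the strong-in-normal, weak-in-cancer
phenomenon planted at a strength that remains resolvable in the smallest
cohort, where the sampling standard deviation of r is large enough that a
moderate planted contrast (say 0.8 → 0.3) would be misclassified in some
cohort on a non-negligible fraction of runs — an intersection screen over
12 cohorts fails if even one cohort flips, so the planted contrast must
dominate small-cohort sampling noise for recovery to be a meaningful test
of the pipeline rather than of luck.

What the generator does *not* emulate: negative-binomial count noise,
GC/length bias, batch effects, dropout, and the dense empirical
gene-gene covariance of real tissue (background genes are independent).
Passing recovery tests therefore demonstrate that the pipeline's logic is
correct and well-calibrated against known truth — not that real cohorts
would yield five pairs, nor that the thresholds are optimal for TCGA
data.

## PPI stage

BioGRID tab files (classic and tab2/tab3 headers) are parsed by official
symbol into an undirected simple graph: evidence lines collapse to one
edge, self-interactions and empty-symbol rows are dropped and counted.
No filtering by experimental system is applied by default (physical and
genetic interactions both kept); a column filter exists. The
direct neighborhood of a seed set keeps edges incident to at least one
seed; a seed–seed edge counts once. Headline interaction counts are
version-pinned to whatever interaction file is supplied — the operation
reports what the file yields, nothing is hard-coded. Exports are SIF and
GraphML (with a boolean seed attribute that survives a round-trip), both
Cytoscape-readable; layout and rendering are left to Cytoscape.

## Problem sizes in the test suite

The suite validates against independent oracles (brute-force Poisson
likelihoods, the Σ-formula Pearson evaluation, a straight-line
re-implementation of the classifier on a 41×41 grid, exhaustive edge
scans) at small n, and runs the full study-shaped recovery — 12 cohorts,
127 genes, published sample sizes — over ten seeds, asserting full
recovery of planted structure with at most one false positive on at least
nine. Monte-Carlo calibration checks (LRT null level, Fisher z type-I
error) use 2000 replicates, sized to bound the nominal 5% level within
[0.035, 0.065].

## Known limitations

* The Poisson LRT on rounded normalized values is a single defensible
  reading of "a likelihood-ratio test on expression"; tools built on
  negative-binomial models will give different p-values on real data.
* Pearson correlation captures linear association only; rank-based or
  partial correlations are out of scope.
* The consistency screen is an intersection — one noisy cohort can veto a
  real pair. With many small cohorts, users should inspect
  `require_all = FALSE` output as well.
* Gene symbols are matched verbatim; panels and expression tables must
  agree on nomenclature beforehand.
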