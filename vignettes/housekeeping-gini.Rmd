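---
title: "Scoring housekeeping genes with two Gini axes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring housekeeping genes with two Gini axes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkgini)
```

## The model

A housekeeping gene, for the purposes of this package, is a protein-coding
gene whose expression is (a) present — its average TPM across tissues
exceeds a floor — and (b) *equal* across observations, where equality is
quantified by the Gini index. For a vector of non-negative expression
values $x_1, \dots, x_n$ with mean $\mu > 0$,

$$G = \frac{\sum_{i}\sum_{j} |x_i - x_j|}{2 n^2 \mu},$$

the mean absolute pairwise disparity normalised to $[0, 1]$. $G = 0$ iff
all values are equal; the attainable maximum for a sample of size $n$ is
$(n-1)/n$, when a single observation carries all the mass. The Gini index
is non-parametric, scale-invariant, and — unlike the coefficient of
variation — well behaved when many observations are exactly zero, which is
routine in TPM data.

The package's central idea is that one Gini value per gene is not enough.
It scores each gene on two axes:

* **Gini-subject**: $G$ over the pooled samples of every tissue in the
  active tissue set. Donor variation and tissue variation both inflate it.
* **Gini-tissue**: $G$ within each tissue's samples separately, giving a
  gene-by-tissue grid. Only donor-to-donor variation inflates it. A gene
  passes the *tissue axis* when its Gini-tissue is below the threshold in
  every scored tissue.

The two axes dissociate in an informative way: a gene can be tight within
every tissue yet shifted between tissues (it passes the tissue axis and
fails the subject axis — the testis-restricted pattern), and a gene can
look acceptable pooled while being driven by one heterogeneous tissue.
The conventional tissue-level Gini over per-tissue mean TPMs
(**Gini-TPM**), the tissue specificity index
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$ and the coefficient of variation
are computed alongside as diagnostics; none of them gates a call.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tpm_cutoff` | 0.05 | TPM | expression floor on the unweighted mean of per-tissue mean TPMs; strictly-above retains |
| `gini_threshold` | 0.2 | – | housekeeping threshold on both axes |
| `call_mode` | `"lt"` | – | strict `<` for calling |
| `pass_mode` | `"le"` | – | `<=` for the tissue-pass-count column |
| `bin_edges` | 0.05 … 100 | TPM | expression-group boundaries for the Gini-by-expression summary |

The expression average behind the filter is the *unweighted mean of
per-tissue means*, not a grand mean over samples: with donor counts
ranging over two orders of magnitude, a sample-weighted mean would let the
largest tissues decide which genes count as expressed. The same unweighted
mean is what score tables report as a gene's average TPM.

Two comparison-mode defaults coexist deliberately: calls use strict `<`
while the per-gene tissue-pass count uses `<=`. These mirror the two
printed conventions such thresholds appear under in practice; both are
parameters, both are recorded in every output's provenance header, and on
boundary-valued data they differ by exactly the boundary genes (this is
under test).

Undefined scores are `NA`, never imputed: a tissue with fewer than two
samples has no Gini-tissue; a sex stratum with fewer than two samples has
no sex-stratified score; a zero-mean vector has no CV; an all-zero profile
has no Tau. `NA` cells are excluded from pass counts and from the
"passes in every tissue" rule (a gene must still pass in at least one
defined tissue). All-equal vectors — including all-zero — have Gini 0 by
convention: equality is the minimum of the index, and no epsilon shift is
applied because TPM zeros are real.

## Numerical choices

* `gini()` uses the sorted identity
  $G = 2\sum_i i\,x_{(i)} / (n \sum_i x_i) - (n+1)/n$, O(n log n), needed
  for pooled vectors of ~10^4 samples; `gini_pairwise()` is the literal
  O(n²) definition. The test suite holds them to 1e-12 relative agreement
  against an independently written brute-force oracle on 1,000 random
  vectors, and checks scale invariance, permutation invariance, the
  $(n-1)/n$ bound, and that transferring mass from a richer to a poorer
  observation never increases $G$.
* The population ($n^2$-denominator) estimator is the default; the
  unbiased $n(n-1)$ form sits behind `unbiased = TRUE`. The population
  form is what the widely used single-file public implementations of the
  index compute, so scores are comparable with published values.
* Tau is computed on the raw (not log) vector of per-tissue mean TPMs —
  the index's standard usage. CV in the score table is over pooled
  samples, the same axis as Gini-subject; per-tissue CVs are computed in
  the report for the within-tissue Gini/CV agreement.
* Expression bins: the 11 default boundaries
  {0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100} are interior boundaries
  over $[0, \infty)$, giving 12 half-open groups with assignment-to-the-
  higher-bin on a boundary. The lowest group, $[0, 0.05)$, is empty after
  the expression filter; the top group collects genes above 100 TPM. The
  boundaries are configuration, not doctrine.
* GCT values are written with `%.17g`, so a write/read cycle is
  value-identical; this is also what makes whole result bundles
  byte-reproducible.

## What the synthetic cohort emulates

`sim_config()` defines a 20-tissue cohort with strongly unbalanced donor
counts (400, 200, 150, … 6, 4; 1,472 samples in total, drawn from a pool
of 1,000 donors, two-thirds male) and 2,000 genes in seven planted
classes. Values are log-normal per class; zeros come from per-class
dropout. This scale was chosen so that the full pipeline plus the test
suite runs in seconds while every qualitative contrast of interest is
decisively out of the noise; the vignette quotes no number that the tests
or the acceptance script do not themselves recompute.

| class | n | construction | expected behaviour |
|---|---|---|---|
| stable_housekeeping | 120 | shared log-mean, within-tissue sd 0.08, between-tissue sd 0.05 | passes both axes (Gini ≈ 0.05–0.11) |
| tissue_specific | 60 | high in one designated tissue, dropout + tiny leak elsewhere | fails both; Gini-TPM ≈ (n−1)/n; Tau ≈ 1 |
| within_tissue_stable_tissue_variable | 150 | within-tissue sd 0.08, between-tissue sd 1.5 | tissue axis yes, subject axis no |
| heterogeneous_marker | 100 | sd 1.2 in the designated heterogeneous tissue, 0.25 elsewhere | fails the tissue axis there |
| sex_dimorphic | 30 | male sd 0.8 vs female sd 0.3 in the designated tissue | male Gini-tissue > female |
| silent | 100 | exact zeros | exactly the genes the 0.05 filter removes |
| background_noncoding | 1,440 | 95% dropout, tiny values | excluded by biotype; near-1 Gini-subject |

Two designated tissues shape the per-tissue summary, via a per-tissue
dispersion multiplier applied to the within-tissue log-sds: the largest
tissue (multiplier 2.5) plays the role of a heterogeneous, blood-like
tissue and should have the maximal mean Gini-tissue and the fewest
housekeeping genes; the second largest (multiplier 0.2) is the quiet
cerebellum/testis analogue and should have the minimal mean Gini-tissue.
The quiet multiplier is deliberately aggressive: small tissues (4–10
donors) are biased *downward* in sample Gini simply by $n$, and the quiet
tissue must undercut them by margin, not luck. These expectations were set
by computing the expected Gini of each class analytically (for a
log-normal with log-sd $\sigma$, $G = 2\Phi(\sigma/\sqrt 2) - 1$) before
any data were drawn, and they hold across seeds. One consequence worth
noting: the home-tissue dispersion of a tissue-specific gene is its own
class parameter and does not inherit the tissue multiplier — the
multiplier models donor heterogeneity of broadly expressed genes, and
letting it inflate a marker gene's home tissue would conflate the two
classes.

Randomness is structured as one root seed for the cohort skeleton
(donors, sexes, sample assignment) plus a per-gene substream derived by a
stable polynomial hash of the gene id folded with the root seed (kept
below 2³¹). Adding a gene class therefore never perturbs the values of
existing genes, and the same seed reproduces the cohort — and any GCT
written from it — byte for byte.

### What passing tests do and do not show

The generator produces clean log-normal donor variation with independent
samples. Real cohorts have donor effects correlated across tissues (the
same individuals contribute many samples), batch and ischemic-time
covariates, count noise at low TPM, and annotation drift — none of which
are modelled. Recovery of the planted stable class at precision and
recall ≥ 0.9 therefore validates the *machinery* (filtering, scoring,
thresholding, set logic), not the biological completeness of any real
housekeeping list. Claims about real tissue cohorts require running the
pipeline on the real inputs through `read_gct()`/`assemble_cohort()`,
for which the full-scale tissue registries (`tissue_preset("gtex52")`,
`tissue_preset("major27")`) and the PAR-Y/biotype machinery are provided.

## Genuinely open design points, and the choices made

* **Samples vs donors.** Pooled scoring treats every sample as one
  individual; a donor contributing two samples to one tissue counts
  twice. No collapsing is done — each expression column is one
  observation — and subject identity is used only for sex stratification.
* **PAR-Y detection** accepts either the `_PAR_Y` id suffix (the
  expression-matrix convention) or a chrY record with an identically
  identified chrX twin (plain GFF3), so either input style deduplicates
  to the same catalog.
* **Re-filtering on subsets.** Restricting to a tissue subset recomputes
  the expression filter on that subset's averages rather than reusing the
  full-cohort gene list, because the tissue-mean average changes with the
  denominator.
* **No multiple-testing correction** is applied to the two group
  comparisons the report runs (coding vs non-coding, paired
  subject-vs-tissue axis): they are two planned single comparisons, and
  the report records them as such.
* **Degenerate t-tests.** `compare_groups()` resolves zero-variance
  inputs analytically (statistic 0 and p = 1 for identical inputs; ±Inf
  and p = 0 for a constant non-zero shift) using the same numerical guard
  `t.test()` applies, instead of erroring mid-pipeline.

## Known limitations

* Gini estimates from tissues with a handful of donors are biased low and
  noisy; the package reports them (with their sample sizes alongside)
  rather than correcting them, and the unbiased estimator flag is a
  palliative, not a fix. Interpreting per-tissue housekeeping counts
  without their donor counts is a mistake the per-tissue summary table is
  designed to prevent.
* A single Gini threshold across tissues is blunt: tissues differ in
  composition heterogeneity, so the same 0.2 means different things in
  blood and cerebellum. The threshold is a parameter everywhere precisely
  because of this.
* The pipeline consumes TPM matrices as given; no batch correction,
  covariate adjustment or cross-cohort harmonisation is attempted, and
  non-coding genes are excluded by a binary biotype string match.
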