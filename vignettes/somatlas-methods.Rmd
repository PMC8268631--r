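---
title: "Molecular cartography with somatlas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular cartography with somatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatlas)
```

## The portrayal model

`somatlas` analyses paired bulk cohorts — a gene × sample expression matrix
(log10 scale) and a promoter methylation beta matrix — by *portrayal*: genes
are treated as points in sample space and compressed onto a K × K
self-organizing map (SOM). Each map unit carries a *metagene*, a prototype
profile across samples; a *portrait* is the K × K image of one sample's
metagene values, with positive pixels marking genes up-regulated relative to
their cohort mean. Because the two layers are trained independently, the
integration stages (covariance maps, the coupled spot network) work at the
gene level and never assume that the two grids align.

Training is **batch SOM**: each epoch assigns every gene to its Euclidean
best-matching unit (BMU), then replaces every codebook vector by the
Gaussian-kernel-weighted mean of the gene profiles, with the kernel radius
annealed linearly and then held fixed for the final epochs. We chose the
batch formulation over online updates because it is deterministic given the
data and parameters — no update-order dependence — and an order of magnitude
faster in vectorized R. Three further choices remove run-to-run variance:

* **Initialization** is deterministic: the codebook is spanned by the first
  two principal axes of the gene cloud (sign-fixed SVD), the first axis laid
  along the longer grid side. Random initialization remains available and is
  seeded.
* **Tie-breaking**: BMU ties go to the lowest unit index.
* **Empty units** keep their codebook vector; they simply host no genes.

The stored gene → unit assignment is the one that produced the final
codebook, so at radius zero the codebook vectors are exactly the unit means
of their member genes and the gene-count-weighted codebook total equals the
(zero) grand total of the row-centered input.

### Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `grid_k` | 30 (50 for large cohorts) | units/side | 30 × 30 suits ≤ ~10k genes; a `c(rows, cols)` pair gives rectangular grids |
| `epochs` | 40 | — | batch epochs; recovery analyses in this package use 25, which is past the point where assignments stabilize at these problem sizes |
| `radius_start` → `radius_end` | `grid_k / 2` → 0.5 | grid units | linear anneal; 0.5 keeps just-noticeable neighbor smoothing |
| `freeze_epochs` | 5 | — | final epochs at the frozen radius; quantization error (QE, mean squared gene-to-BMU distance) is expected to settle monotonically here |

At a fixed kernel the batch update minimizes the kernel-smoothed distortion,
not the QE itself, so QE may wiggle at machine precision even when training
behaves; the monotonicity check therefore allows a relative slack of
`1e-8 · QE[1]`.

## Preprocessing

Quantile normalization forces every sample to share the across-sample mean
order statistics; ties receive the mean of their tied ranks' normalized
values, which makes the operation idempotent and exactly reproducible.
Promoter methylation is gene-centric: CpGs inside the strand-aware window
from 2 kb upstream to 200 bp downstream of the TSS (closed, 1-based;
mirrored for minus-strand genes because "upstream" is 5') are averaged per
gene, with missing betas excluded pairwise. Genes on chrX/chrY are removed
before mapping to avoid sex-composition artifacts — the female-difference
map would otherwise light up wherever X-linked genes cluster. Array
calibration and background-noise correction are upstream responsibilities:
they are chemistry-specific and the package takes calibrated log-scale
values (a `log10(x + 1)` guard transform is provided for raw intensities).

## Spots, calls and implication

Spot modules are segmented on the *summary map* — the pixel-wise maximum of
the group-mean portraits (minimum for the "under" direction). Units strictly
above the nearest-rank `q`-quantile of all unit values form connected
components; components smaller than `min_size` are dropped and the rest are
labeled A, B, … by descending peak. All quantiles in the package use the
nearest-rank definition (no interpolation) so thresholds are bit-exact
across platforms. Defaults are `q = 0.98`, `min_size = 3`, 8-connectivity —
the conservative, visually faithful setting for exploratory portraits.

The **recovery analyses** on synthetic cohorts use `q = 0.95` with
4-connectivity instead, for a geometric reason: six planted modules hold 12%
of the genes, so their combined map territory is far larger than the top 2%
of units — a 0.98 threshold cannot cover six blobs, and on a 30 × 30 grid
two distinct blobs frequently touch at a corner, which 8-connectivity would
merge into one spot. This is an operating-point choice for a cohort whose
module count is known by construction, not a change to the package
defaults.

A spot is *called* in a sample when the sample's mean metagene value over
the spot units exceeds the nearest-rank 0.90 quantile of that sample's own
unit values — a rank threshold invariant to per-sample shifts. Implication
edges between spots require both directional confidences
`conf(A→B) = |A∧B| / |A|` to exceed 0.5, matching the undirected reading of
co-occurrence.

Cross-mapping sends one layer's spot genes into the other layer's map and
summarizes their spread as normalized Shannon entropy over bins: one bin
per target spot plus **one bin per background unit**, normalized by
`log(n_bins)`. Keeping background units separate is essential — a single
background bin would score genes scattered across a thousand unstructured
units as "concentrated", inverting the melting signature the score exists
to detect.

## Gene-set scoring

The GSZ score standardizes a set's summed value within each sample against
hypergeometric sampling of `n` genes from that sample's `N` values:

$$\mathrm{GSZ}_s = \frac{\sum_{g \in \mathrm{set}} e_{gs} - n\,\mu_s}
{\sqrt{n\,\sigma^2_s\,(N-n)/(N-1)}}$$

with population variance `σ²` and the convention that a zero-variance
sample scores 0. This variant is exactly testable: its mean and variance
under random sets are 0 and 1 *by construction* (verified by exhaustive
subset enumeration in the tests), and it is invariant to shifting or
rescaling a sample's column. Whether historical GSZ formulations add
variance-shrinkage terms is left aside deliberately; the implemented
statistic is the plain hypergeometric set-sum z-score and is documented as
such. Set-overlap screening uses the one-sided hypergeometric tail
(enrichment) with a Haldane 0.5 correction on zero cells of the odds-ratio
table; two-sided testing is available via `alternative = "two.sided"`.

## Phenotype maps

The prognostic map fits, per unit, a univariate Cox model with the unit's
metagene values (standardized to unit variance) as a continuous covariate:
the stored log hazard ratio is per metagene SD. We chose the continuous
covariate over a high/low dichotomy because it needs no arbitrary cut and
calibrates correctly under the null (~5% of units at |z| > 1.96 with
permuted or hazard-free survival, which the tests verify). The estimator is
Newton–Raphson on the Breslow partial likelihood (|score| < 1e-8 or 50
iterations; non-convergence, < 2 events, or a constant covariate flag the
unit invalid rather than zeroing it). Breslow ties were chosen because they
are exactly reproducible by a grid-search oracle; Kaplan–Meier curves and
log-rank tests delegate to the survival package. Phenotype maps carry no
multiple-testing correction — they are descriptive visualizations; per-unit
z values are exported so users can apply FDR control downstream.

The female difference score selects, per unit, the samples in the top
quartile of that unit's metagene values (strictly above the nearest-rank
0.75 quantile) and reports
`100 · (pct_female_selected − pct_female_all) / pct_female_all` — a
relative, "percent-of-percent" deviation. Units where no sample exceeds the
quantile (flat metagenes) are flagged invalid.

## Expression–methylation integration

The covariance map colors each unit by the mean, over its member genes, of
the population (1/n) covariance between the gene's expression and its
promoter beta across shared samples; population moments keep the statistic
descriptive and consistent with the variance conventions used elsewhere.
The coupled spot network pairs expression and methylation spots whose gene
sets overlap beyond chance (one-sided Fisher `p < 1e-3`, universe = genes
present in both trained models) *and* whose per-sample spot profiles are
anti-correlated (`r < 0`; any negative correlation, since the biology
claims direction, not magnitude). Connected components of this network are
the consensus coupling modules.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline is built for,
with defaults chosen as the study conditions of the recovery analyses:

* 5,000 genes × 120 samples, 6 subtypes in equal blocks, 6 planted modules
  of 100 genes — one module activated (effect 1.0 log10 units ≈ 10-fold)
  per subtype. One module per subtype keeps every module's sample-space
  profile distinct; modules sharing an activation pattern would be
  indistinguishable in principle, for any method.
* Gene-level noise sd 0.4 (log10), a moderate-noise regime: within-module
  gene correlation ≈ 0.5.
* Half the modules are methylation-coupled: their genes' promoter CpGs
  follow `clamp(0.5 − 0.3 · activity + N(0, 0.05), 0, 1)` — hypomethylated
  where active, the canonical repressive promoter coupling. Methylation
  spots are therefore detected in the "under" direction.
* 5 CpGs per gene placed uniformly inside the promoter window, so the
  aggregation path is genuinely exercised; 2% of background genes sit on
  chrX/chrY to exercise the sex filter.
* Survival is exponential with baseline median 5 time units
  (`λ0 = log(2)/5`) and per-module log-hazards (default: log 2 on module
  1); censoring is Uniform(0, T_c) with T_c solved numerically for the
  target censored fraction (default 0.3).
* Module activity of a sample is the activation entry of its subtype — a
  block model, matching the bulk-cohort resolution of the analyses; no
  within-subtype mixtures.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: probe-level noise and calibration
artifacts, copy-number dosage, overlapping or nested modules, gradual
(non-block) subtype structure, cell-type mixtures, and CpG-level coupling
heterogeneity within a promoter.

## Problem sizes and numerical conventions

Recovery and calibration analyses run the default cohort with 30 × 30
grids and 25 epochs across 10 generator seeds; the worked examples and
enumeration oracles (GSZ, Fisher, Cox) run at hand-checkable sizes. All
randomness derives from explicit integer seeds; rerunning any stage with
the same configuration reproduces byte-identical outputs (the pipeline
manifest records MD5 checksums). Degenerate inputs have defined behavior
throughout: flat summary maps yield zero spots, zero-variance samples score
0 in GSZ, constant covariates and event-free survival flag Cox fits
invalid, and beta values clamp to [0, 1] at generation.

## Known limitations

* Spot labels are per-run; no correspondence across independently trained
  maps is asserted (cross-map comparisons are gene-based by design).
* The Cox map is univariate; confounding between correlated units or with
  age/sex is not adjusted for.
* The GSZ variant omits variance-shrinkage corrections of some historical
  formulations.
* Grids are planar (no toroidal topology) and fixed-size (no growing
  maps); GPU training is out of scope.
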