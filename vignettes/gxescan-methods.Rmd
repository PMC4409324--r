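---
title: "Models and methods behind gxescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gxescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

gxescan analyses multi-environment drought phenotype trials of a fixed
diversity panel — typically ~20 rice genotypes spanning aus, indica and
japonica groups — together with the panel's introgression-block
structure over 100 kb genome windows. This vignette explains the models
the package fits, the parameters that matter, the design choices that
were genuinely open, and what the synthetic-data tests do and do not
demonstrate about real field data.

## From plots to genotype means

Plot-level observations (genotype × environment × replicate block) are
reduced per environment with the additive fixed-effect model

$$y_{gb} = \mu + G_g + B_b + \varepsilon_{gb},$$

and the least-squares genotype mean is the fitted value averaged over
the block levels present. For balanced data this equals the arithmetic
mean, and it coincides with mixed-model (random-block) LS means in that
case; we deliberately use the fixed-effect fit because the downstream
analyses only consume the adjusted means, and the fixed/random
distinction matters mainly for standard errors we never use. The
equivalence is only exercised on balanced and near-balanced designs in
the tests; for severely unbalanced real experiments a dedicated mixed
model would be preferable. Environments with fewer than two genotypes
carry no contrast and are dropped with a warning. When a genotype
occurred in only some blocks of an environment, the additive fit is
used as-is, with no further adjustment.

Stress-response indices are computed exactly as printed on field
report scales: ratio reductions `(control − stress)/control × 100` for
shoot biomass, RDW and grain yield, a ratio increase for MRL, and a
*percentage-point difference* (not a ratio) for %DR. A zero control
value makes a ratio index undefined; it is flagged as `NaN` with a
warning rather than dropped, so downstream summaries cannot silently
lose genotypes. `% deep roots` is the mass fraction below a depth
cutoff (20 cm in most systems, 30 cm in deep cylinders); the cutoff
must be a sampled bin boundary — no interpolation is attempted, because
root mass is strongly non-uniform within bins.

## AMMI and GGE decompositions

For a complete genotype × environment table the AMMI model is

$$Y_{ge} = \mu + G_g + E_e + \sum_k \lambda_k \alpha_{gk} \gamma_{ek}
          + \varepsilon_{ge},$$

fit by mean polish (row/column means on a complete table are the
least-squares main effects) followed by SVD of the doubly-centered
residual. Sums of squares partition exactly:
`ss_G + ss_E + ss_GxE = ss_total`, and `Σλ_k² = ss_GxE`. Per-PC
percentages are `λ_k²/Σλ² × 100` of the interaction.

The "location standardized" (GGE) variant centers **and scales** each
environment column before one SVD of the standardized table, whose
axes then mix G and G×E. Scaling by the environment standard deviation
is our interpretation of "location standardized" — the convention used
for standardized GGE biplots — and makes the result invariant to any
per-environment affine rescaling (units, site-level offsets). With the
genotype main effect retained, environments with a shared genotype
ranking load on one side of PC1.

Numerical conventions:

* **Sign fixing.** SVD score signs are arbitrary; we flip each axis so
  the largest-magnitude genotype score is positive, making outputs
  reproducible across BLAS implementations.
* **Weighting.** SS are computed on cell means, equally weighted by
  default; when replicate counts are available (`ls_means` attaches
  them) `weighted = TRUE` weights each cell by its replication. The
  default is unweighted because the decomposition operates on the
  means table, and unequal weighting changes only the SS bookkeeping,
  not the scores.
* **Biplot scaling.** `tidy()` returns symmetric-scaled coordinates
  (`√λ` on each mode), the common biplot compromise.

## Missing cells

Panels are rarely complete (germination failures, photoperiod-sensitive
genotypes with no yield). Cells missing completely at random are filled
before decomposition by an EM-style scheme: initialize at
`row + column − grand` mean, iterate that additive fill to its fixed
point — which recovers exactly additive tables exactly — then alternate
an additive fit with a rank-`k` SVD reconstruction of the residual,
updating only missing cells, until the largest change falls below
`tol = 1e-8` (cap 500 iterations, non-convergence returns the last
iterate with a warning). The additive pre-pass matters: with a single
missing cell, any filled value makes the residual exactly rank one, so
a low-rank iteration started from raw means would accept its starting
point; anchoring at the additive fixed point resolves that degeneracy
toward the parsimonious solution. The default rank is 2, matching the
two interpreted biplot axes. Observed cells are never altered.

## Dendrograms

Genotype and environment groupings are summarized by average-linkage
agglomeration over Euclidean distances of standardized profiles,
pairwise-complete over shared observed cells (distances rescaled by
the fraction of shared columns, as `stats::dist` does). The
agglomeration is written out explicitly rather than delegated so that
ties break deterministically — the lowest-index pair merges first —
because merge order on tied heights is otherwise implementation
defined and would make serialized trees non-reproducible. Average
linkage is the package's choice; no linkage is canonical for this use.
Trees serialize to newick via ape.

## Correlation structure

Experiment-by-experiment Pearson correlations use pairwise-complete
deletion (experiments share only subsets of genotypes; listwise
deletion would discard most pairs), with two-sided p from the t
transform on `n − 2` df. Counting "significantly correlated partner
experiments" uses raw `p < 0.05` with **no multiple-testing
correction** — this mirrors the descriptive counting convention the
analysis reproduces and is stated here deliberately. Pairs with fewer
than three shared genotypes or a zero-variance member are reported
missing, never as `r = ±1`.

## Introgression-block association scan

Each 100 kb window's binary indicator is tested against each trait ×
experiment phenotype by simple regression; for a binary regressor the
one-way ANOVA F equals the squared pooled-variance two-sample t, an
identity the tests verify to 1e-8. Windows with a minor class below 2
carriers are skipped and tallied — a 1-vs-19 regression is formally
computable but a single outlier genotype decides it. Donor groups
(aus/indica/japonica) are scanned as separate tracks. Filtering uses
the strict raw cutoff `p < 0.001`, again uncorrected by design;
book-ended significant windows merge into regions per (trait,
experiment, donor group) track; and hot spots are maximal runs of
windows where ≥ 5 distinct (trait, experiment) combinations co-locate.
"Aligned traits" counts (trait, experiment) combinations — not traits
alone — because each experiment contributes an independent phenotype
realization; the hot-spot record reports the full combination set, the
per-window depth profile, and coordinates in 0-based half-open bp
(printed as Mb with one decimal in reports).

## QTL enrichment

A region of `n` windows is tested for over-representation of a QTL
annotation covering `K` of the `N = 3680` annotated windows genome-wide
with the hypergeometric upper tail

$$p = \sum_{k \ge h} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

the one-tailed Fisher's exact test in the enrichment direction (all
published overlaps of interest are over-representations; the depletion
tail is not reported). The sum is accumulated in log space from
log-gamma binomial coefficients, so p-values at the 1e-25 scale of
dense overlaps are exact to working precision. An independent exact
oracle (`hypergeom_upper_tail_exact`) enumerates the same tail in
64-bit integer rational arithmetic via Pascal's triangle — exact for
populations up to 62, where `C(62,31) < 2^63` — and the test suite
sweeps *every* feasible configuration with `N ≤ 60` against it.
`population_total` is a configuration value (3680 by default), not
derived from the annotation union, since published tables fix it.
Reported p-values are formatted at 3 significant figures.

## The synthetic-data generator

`sim_phenotypes()` draws

$$y_{geb} = \mu + G_g + E_e + \textstyle\sum_k \lambda_k \alpha_{gk}
\gamma_{ek} + b_{eb} + \varepsilon_{geb}$$

with every structural component *empirically* standardized and scaled
to its requested variance fraction: genotype and environment effects
are centered unit-variance draws, and the interaction is built from
random orthonormal factors (QR of a Gaussian matrix alongside the
intercept) and is therefore exactly doubly centered. Main effects and
interaction are thus exactly orthogonal and the realized SS partition
matches the request up to error-term sampling noise only. Block
effects are i.i.d. normal within environment; because the four
variance fractions must sum to one, blocks take a `block_share`
(default 25%) slice of the error budget, so a plot-level ANOVA that
ignores blocks still sees the requested error fraction. Missingness
deletes whole genotype × environment cells completely at random
(mirroring genotypes absent from an experiment); exclusion lists
remove named genotypes everywhere. Causal windows shift carrier
genotypes' main effects by the stated multiple of the total phenotype
SD, with carriers fixed at half the panel so the association contrast
is well powered at the stated effect size.

What the generator does **not** emulate: spatial field trends,
genotype-specific missingness (photoperiod sensitivity is *not*
random), non-normal measurement error, correlated traits, linkage
between windows, and population structure in the indicator matrix
(windows are independent draws). Passing tests therefore demonstrate
algorithmic correctness under the stated model, not robustness to
those real-data features.

## Problem sizes and study conditions used in the tests

The acceptance-style checks run at sizes chosen to exercise the
published design while staying desk-scale: the variance-fraction
recovery uses a 19 × 19 genotype × environment design with 4 blocks
and 20 simulation replicates, targeting the G : E : G×E ratio
11.3 : 59.3 : 29.4 of the yield analysis; since the published partition
is of cell-mean SS with no printed plot-level residual, the structural
fractions are scaled by 0.96 and a 4% plot-level error fraction added —
small enough that 4-block cell means remain structure-dominated (the
error leaks ~1% of total SS into the interaction residual), large
enough that measurement noise is present. Null calibration of the scan
uses 10,000 windows against 100 independent null phenotype vectors of
20 genotypes (100 windows each) rather than one shared vector, keeping
the p-values close to independent for the Kolmogorov–Smirnov check.
The exact-enumeration sweep covers every feasible hypergeometric
configuration with population ≤ 60 (~0.5 million tails).

## Known limitations

* The fixed-effect LS means differ from random-block mixed-model means
  under severe unbalance; the package targets the balanced to
  near-balanced designs it simulates.
* AMMI axis significance testing (Gollob/F-ratio style) is out of
  scope; PC shares are descriptive.
* The scan tests windows marginally; no LD-aware or multi-window model
  is attempted, matching the procedure it reproduces.
* Published genome-scale counts (tens of thousands of significant
  blocks across 3680+ windows, specific Mb hot-spot coordinates)
  require the original panel genotypes and phenotypes and are
  explicitly not reproduced here; the pipeline reproduces the
  *procedure* and its desk-scale statistical behaviour.
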