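---
title: "Methods: multi-stage drought-tolerance screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage drought-tolerance screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

## The trial model

All estimators in this package assume a balanced split-plot
multi-environment trial: irrigation regimes (full vs limited) on main
plots, genotypes on subplots, `r` replicate blocks within each of `s`
seasons. Plot values follow the additive model

$$ y_{gser} = \mu + S_s + I_e + (SI)_{se} + b_{sr} + b_{ser} + G_g +
   (GE)_{g,se} + \varepsilon_{gser}, $$

with genotypic effects $G_g$ (variance $\sigma^2_g$, correlated across
traits), genotype-by-environment effects $(GE)$ independent per
season-regime cell (variance $\sigma^2_{g\times e}$), and plot residuals
(variance $\sigma^2_{re}$). Season is treated as random, genotype and
regime as fixed. `combined_anova()` decomposes the total sum of squares
into the classical ten sources; because the design is balanced the
decomposition is orthogonal and exact, and unbalanced input is rejected
rather than imputed.

## Genetic parameters

`variance_components()` applies the moment estimators
$\hat\sigma^2_g = (MS_G - MS_{G\times E})/(re)$,
$\hat\sigma^2_{g\times e} = (MS_{G\times E} - MS_E)/r$,
$\hat\sigma^2_{re} = MS_E$. Two conventions are deliberately configurable
because published trait tables of this kind are rarely derivable from
their own ANOVA tables under a single reading:

- **Which interaction mean square is $MS_{G\times E}$.** The default pools
  the three interaction mean squares (S×G, I×G, S×I×G) weighted by their
  degrees of freedom; any single interaction can be chosen instead
  (`convention = "sxg"`, `"ixg"`, `"sxixg"`). Under the generator's model
  all three interactions have the same expectation
  $\sigma^2_{re} + r\,\sigma^2_{g\times e}$, so pooling is the
  minimum-variance choice and recovers the simulation truth.
- **The number of environments `e`.** The default counts each
  season-regime cell as an environment (`e = s × 2`, here 4); counting
  seasons only (`e = s`) is available via `e_convention = "seasons"`. The
  cell convention makes the four-environment worked example
  $h^2 = 4/(4 + 1/4 + 1/12) \approx 0.9231$ hold at the default design.

Negative moment estimates are truncated to zero (standard practice) and
the truncation is recorded on the returned object. Genetic parameters
follow the coefficient-of-variation convention with square roots,
$GCV = 100\sqrt{\sigma^2_g}/\bar x$ and $PCV = 100\sqrt{\sigma^2_p}/\bar x$
with $\sigma^2_p = \sigma^2_g + \sigma^2_{g\times e}/e + \sigma^2_{re}/(re)$
on the genotype-mean basis. This reading is fixed by the internal identity
$h^2 = (GCV/PCV)^2$, which published tables of these parameters satisfy;
`genetic_parameters()` preserves it to machine precision, and the test
suite asserts it. The selection differential defaults to `k = 2.06`
(5% selection intensity); the grand mean is the unweighted mean of all
plot observations, which in a balanced design equals the mean of the four
season-regime means.

## What the synthetic generator emulates — and what it does not

`simulate_trial()` with the default `trial_design()` reproduces the study
conditions of a two-season bread-wheat screening trial: 25 genotypes, two
irrigation regimes, three replicates, and a 28-trait panel spanning leaf
water status (LWC, RWC, LEWT, CT), gas exchange (Pn, Gs, Ci, E, WUE,
WUEi, Ls), morphology (GLN, FLA, GLA, LAI, DSW, DLW, TDW), phenology
(DH, DM, GFD) and yield components (NS, PH, SL, NSS, NKS, HKW, GY).
Per-trait grand means, stress shifts and coefficients of variation are
calibrated to the magnitudes such trials report; canopy temperature and
the water-use-efficiency traits increase under limited irrigation, all
others decrease.

Variance components are derived from the coefficients of variation at the
default scale (r = 3, e = 4): $\sigma^2_g = (GCV\,\bar x/100)^2$, and the
non-genetic mean-basis variance $\Delta = \sigma^2_p - \sigma^2_g$ is
split so the interaction and residual terms contribute equally
($\sigma^2_{g\times e} = 2\Delta$, $\sigma^2_{re} = 6\Delta$). This makes
the simulation-truth heritability exactly $(GCV/PCV)^2$ — the one quantity
the published parameter sets determine unambiguously — while leaving the
split itself a modelling choice, since no self-consistent split can match
every printed table simultaneously.

Genetic correlations between traits are completed from the user-specified
trait-to-yield correlations by the product rule
$\rho_{ij} = \rho_{iy}\rho_{jy}$, giving the rank-one-plus-diagonal matrix
$\rho\rho' + \mathrm{diag}(1-\rho^2)$, positive semi-definite by
construction; a nearest-PSD eigenvalue-clipping projection guards
user-modified targets. Season and block effects are drawn once per level
from zero-mean normals scaled to fractions (defaults 0.5 and 0.25) of
each trait's residual standard deviation — large enough to exercise the
rep(S) and rep(I×S) strata, small enough not to dominate.

Two realism limits matter when interpreting green tests:

- **Traits are censored at zero.** All panel traits are physically
  nonnegative, but a normal model with the calibrated coefficients of
  variation would put a small tail below zero for the most variable
  traits (notably LAI); plot values are therefore truncated at zero
  (`nonnegative = TRUE`). The truncation is inactive for the
  moderate-variability traits used in the estimator-recovery benchmarks.
- **The stress response is uniform across genotypes.** The regime effect
  shifts every genotype equally, and genotype-specific stress response
  enters only through the iid G×E term. Real tolerant and sensitive
  genotypes differ *systematically* in their stress ratios, which is why
  field data yield wide, season-stable membership indices while synthetic
  trials yield tolerance classes driven by G×E noise. Passing tests
  therefore demonstrate that the estimators and classifiers are correct,
  not that tolerance classification on synthetic data is biologically
  meaningful.

## Screening, yield model, membership index

Multicollinearity is diagnosed on aggregated means (genotype means by
default, genotype × season × regime cells in the pipeline): tolerance is
$1 - R^2_j$ from regressing trait *j* on the rest, VIF its reciprocal,
with exact linear combinations flagged infinite. `drop_collinear()`
removes the single worst trait above VIF 10 and recomputes, breaking ties
alphabetically (recorded in the exclusion order). PCA operates on the
correlation matrix; component signs are fixed so each component's
largest-magnitude loading is positive, making output deterministic.
Trait selection uses `|loading| > 0.27` on the first two components —
absolute values, because traits loading negatively (canopy temperature
against yield) are as informative as positive loaders; raw loadings are
used rather than loadings scaled by the singular values.

Stepwise regression enters the candidate with the smallest partial-F
p-value below α-enter = 0.05 and removes entered traits whose p-value
exceeds α-remove = 0.10; both α's are configurable (the classical values
are defaults because the source analyses do not state theirs). Partial R²
is reported as the sequential increment in entry order. Path analysis
standardizes all variables and solves $R_x p = r_{xy}$; the determination
is $R^2 = \sum_i p_i r_{iy}$, reported alongside its direct part
$\sum_i p_i^2$ and the indirect remainder, with residual effect
$\sqrt{1 - R^2}$. Published path tables of this kind are often internally
inconsistent (their printed $\sum p_i r_{iy}$ need not equal their printed
R²); this package implements the standard identities, asserts them on its
own decompositions, and does not attempt to reverse-engineer variant
formulas.

The membership index forms stress/control ratios per genotype × season
from regime means, inverting the orientation (full/limited) for
stress-increasing traits so that larger always means more tolerant —
without the inversion, genotypes that keep canopy temperature low under
stress would rank backwards. Inversion defaults to automatic detection
from the regime-contrast sign and is recorded. Min–max rescaling is
applied within each trait × season slice (the per-year reading), making
each slice attain 0 and 1 exactly. Numerical conventions: a degenerate
slice (zero range) receives 0.5 with a warning; the class boundary at
Fi = 0.8 belongs to HT so the five ranks partition [0, 1] without gaps;
displayed scores round half-up at 3 decimals, but classification always
uses unrounded values. The default trait panel is GLA, LAI, RWC, CT and
is fully configurable.

## Group validation

Validation runs on the genotype × (trait × season) membership score
matrix (8 columns for the default panel; the per-season overall indices
can be selected instead). Ward linkage (`ward.D2` on Euclidean distances)
is the clustering default with UPGMA available; principal coordinates use
classical scaling, whose eigenvalues provably match centered-data PCA for
Euclidean input (asserted at 1e-8). The Mantel test correlates the score
distances with the dendrogram's cophenetic distances by default
(permutation p-value $(\#\{r^* \ge r\} + 1)/(n_{perm}+1)$, delegated to
`vegan::mantel`). Canonical discriminant analysis eigen-solves
$W^{-1}B$ with coefficients scaled to unit pooled within-group variance;
Box's M (χ² approximation — group sizes here are too small for the F
form) gates the classifier at α = 0.05: heterogeneous covariances select
QDA with per-group covariances, otherwise LDA, always with equal priors;
when any group is not larger than the trait count the pooled (LDA)
fallback is used and flagged. MANOVA reports Wilks' Λ with Rao's F
approximation (for a single trait it reduces exactly to the one-way
ANOVA F), plus per-trait least-squares means with unadjusted pairwise
contrasts at α = 0.05 — unadjusted because raw significance is the
convention in these trait-by-trait group comparisons; adjustment can be
layered on by the user. Tolerance classes with fewer than two genotypes
are set aside from the group-based stages (and reported), since neither
a covariance nor a within-group contrast is estimable for a singleton.

## Problem sizes and determinism

The estimator-recovery benchmarks use 200 simulated trials of the
single-trait benchmark design ($\sigma^2_g = 4$, $\sigma^2_{g\times e} = 1$,
$\sigma^2_{re} = 1$, truth $h^2 = 0.9231$); Mantel calibration uses
300–600 null pairs of 10-item matrices at 99 permutations; MANOVA null
calibration uses 200 three-group datasets. These sizes put Monte-Carlo
error comfortably inside the asserted bands while keeping the whole suite
fast on one CPU. Every stochastic step is seeded: `simulate_trial()` uses
a single RNG stream keyed by its seed (traits drawn in fixed panel
order), and `run_pipeline()` reuses its seed for simulation and
permutation tests, so identical configurations reproduce identical
reports.

## Known limitations

- ANOVA-based estimation only: no REML/mixed-model path, no unbalanced
  or missing-plot designs, no narrow-sense heritability.
- The generator draws normal (zero-censored) traits; skewed or discrete
  phenotypes are out of scope.
- Cluster counts, PCA variance percentages and Mantel correlations
  reported for any particular field study depend on unstated input and
  linkage choices; the package treats such quantities as qualitative
  targets and exposes the choices (`linkage`, score columns, Mantel
  pairing) instead of hard-coding one reading.
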