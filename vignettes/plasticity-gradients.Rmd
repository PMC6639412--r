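---
title: "Quantifying cortical plasticity as the complement of connectivity heritability"
author: "connherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical plasticity as the complement of connectivity heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connherit)
```

## The scientific question

Cortical plasticity — the reorganization of neural circuits in response to
experience — can be quantified without a longitudinal design by asking how
far a phenotype has drifted from its genetic blueprint: the fraction of
phenotypic variance *not* explained by additive genetic factors, `1 - h2`.
Applied to resting-state functional connectivity (RSFC) between visual
areas in a twin cohort, this yields a per-connection, and after averaging a
per-area, plasticity estimate that can be regressed on the area's position
in the processing hierarchy. `connherit` implements that full pipeline —
from ROI time series to the gradient models — together with a synthetic
twin-cohort generator with known ground truth, so that every stage is
testable end to end without access to restricted family data.

## The variance-components model

For a phenotype vector `y` over `n` subjects with covariate design `X`, the
twin AE model assumes

    y ~ N(X beta, Omega),   Omega = 2 Phi sigma_g^2 + I sigma_e^2,

where `2 Phi` is the expected-genetic-sharing (kinship) matrix: 1 between
monozygotic (MZ) co-twins, 0.5 between dizygotic (DZ) co-twins, 0 between
unrelated subjects. Heritability is `h2 = sigma_g^2 / sigma_p^2` with
`sigma_p^2 = sigma_g^2 + sigma_e^2`. The covariance model contains exactly
a genetic and a residual term; a shared-environment (C) component is out of
scope and left as an extension point.

Writing `Omega = sigma_p^2 W(h2)` with `W = (1 - h2) I + h2 * 2 Phi`, both
the GLS covariate effects and `sigma_p^2` have closed forms for fixed
`h2`, so the likelihood is maximized over the single bounded parameter
`h2 in [0, 1]`. We profile out both nuisance parameters analytically and
maximize the 1-D profile likelihood with a coarse grid (step 0.05) followed
by golden-section refinement (`stats::optimize`, tolerance 1e-7 on `h2`),
evaluating the boundary points explicitly. This is deterministic,
boundary-safe, and strictly stronger than a multi-start search over a
2-parameter surface: with the nuisances profiled in closed form the
remaining surface is one-dimensional and cheap to bracket globally. The
family-block structure (2x2 blocks) makes each likelihood evaluation O(n).

Significance uses the likelihood-ratio statistic `2(Le - L0)` against the
`sigma_g^2 = 0` model. Because the null pins a variance to the boundary of
its parameter space, the statistic is asymptotically a 50:50 mixture of a
point mass at zero and a chi-square with 1 df; `p = 0.5 P(chi2_1 >= stat)`
for positive statistics. At `stat = 0` the package reports `p = 1` (the
observation falls in the boundary point mass; the most conservative
choice). Some packages report 0.5 instead; this is configurable
(`p_zero_convention`). The null calibration is exact for the
intercept-only model at the study's sample size; when several fixed
covariates are estimated simultaneously the ML (non-REML) likelihood makes
the boundary LRT mildly conservative (rejection ≈ 0.035–0.04 at a nominal
0.05, boundary mass slightly above 0.5) — it never over-rejects. Profile-likelihood 95% intervals invert the LRT at
the standard `qchisq(0.95, 1)/2` drop; the boundary makes them slightly
conservative, which the recovery simulations confirm (coverage at or above
the nominal level across `h2` 0.2–0.8).

Connectivity phenotypes are passed through a rank-based inverse normal
(Blom) transform, `qnorm((rank - 3/8)/(n + 1/4))`, before fitting, keeping
residual kurtosis in the normal range; anatomical phenotypes use covariates
age and sex only, connectivity phenotypes age, sex, mean framewise
displacement, and reconstruction version.

## Connectivity, screening, reliability

Per-subject connectivity is the Fisher z (`atanh`) transformed correlation
between ROI time series after per-run regression of the 12 motion
regressors (6 realignment parameters and their backward differences, first
row zero) plus an intercept. Nuisance regression can be applied per run or on the concatenated
data; the convention is not standardized, and per-run regression is the
default (`regress_per_run = TRUE`)
because it prevents run-boundary artifacts, and it is configurable.
Session-day tables use runs 1–2 (day 1) and runs 3–4 (day 2).

Group-level screening is a one-sample location test of the mean Fisher z
per connection, with the null built by whole-family sign flips: flipping
all members of a family jointly preserves the within-family covariance
while the no-connectivity null makes family blocks exchangeable in sign.
This choice of statistic-plus-flip-scheme is one member of the family of
admissible block schemes; any scheme preserving family blocks would do.
p-values are `(1 + #exceedances)/(n_perm + 1)` (10000 draws by default)
and pass through Benjamini–Hochberg step-up FDR at `q = 0.05`; connections
above the threshold are excluded from all per-area averaging.

Test–retest reliability is ICC(3,1) — two-way mixed, single rater,
consistency — per connection across the two session days; consistency (not
absolute agreement) follows the Shrout–Fleiss (3,1) convention, so a
constant offset between days does not reduce it. The heritability-vs-ICC
control is a Mantel test: squared Pearson correlation of the vectorized
lower triangles over the kept-connection mask, with the null built by
jointly permuting the rows and columns of one matrix (5000 permutations by
default). Masked (screened-out) entries are excluded pairwise: kept-only is the
coherent choice given that heritability is only estimated for kept
connections (using all off-diagonal entries instead is a one-line change).

## Hierarchy and the gradient models

Hierarchical level `eta` is the shortest-path edge count (unit weights,
Dijkstra) from each area to V1, computed per hemisphere with that
hemisphere's V1 as root; `eta(V1) = 0`. Whether such a count should start
at zero or one is a convention, so a `level_offset` flag exists; 0 is the
default. The true 48-area atlas adjacency is not distributable, so the
package ships a synthetic stand-in fixture (24 areas per hemisphere with a
retinotopy-style naming scheme and plausible neighbor structure,
`inst/extdata/visual_areas_edges_synthetic.tsv`); analyses of real data
must supply the real edge list.

Per-area profiles average a per-connection quantity over the area's kept
connections (each connection contributes to both endpoints, SEM across
connections attached). No distance correction is applied: the mean graph
distance from an area to all other areas is essentially constant across
areas, so distance cancels in the averaging. Fits are unweighted: the SEM is
reported alongside, not used as weights, since per-area connection counts
are nearly equal and weighting adds a discretionary choice.

The gradient is tested with nested OLS models, `mean ~ eta` and
`mean ~ eta + eta^2`, each with its overall F-test, compared by the partial
F `((RSS1 - RSS2)/1)/(RSS2/(n - 3))`. The early-visual test restricts the
linear fit to V1, V2d, V2v, V3d, V3v in both hemispheres (10 areas, slope
df = 8).

## The two-component plasticity model

Total plasticity is decomposed as a transient short-term component that
decays up the hierarchy and a sustained long-term component that grows:

    h2(eta) = h_max - a1 exp(-b1 eta) - a2 exp(b2 eta),   a1, b1, a2, b2 >= 0

with `h_max` fixed at 0.5 to absorb measurement noise common to all
levels. Parameters minimize a robust soft-L1 loss
`2 f^2 (sqrt(1 + (r/f)^2) - 1)` of the residuals (scale `f = 0.02`,
roughly the per-area SEM; configurable to plain least squares — "robust
non-linear least squares" names a family, not a loss, so the loss is a
stated choice). Optimization is `stats::nlminb` with non-negativity bounds
from a deterministic 4x4 grid of starts over the decay rates
`b1, b2 in {0.1, 0.5, 1, 2}`; R^2 is always reported on the raw residuals,
not on robust-weighted ones, so fit quality is comparable across loss
choices. On noiseless data the fit recovers generating
parameters to 1e-4.

Component attribution freezes the fitted shapes and fits a single vertical
intercept to a target profile (`target = beta - c1(eta)` or
`beta - c2(eta)`), comparing the two one-parameter models by
`AIC = n log(RSS/n) + 2k` with `k = 2`; only AIC differences matter, so
any consistent convention works. Akaike weights
`exp(-Delta/2)/sum exp(-Delta/2)` give the relative likelihood of the
short- versus long-term component as the explanation of, e.g., the ICC
gradient (expected: short) and anatomical-heritability gradients
(expected: long).

## The synthetic study conditions

The generator reproduces the cohort and design of the real study — 123 MZ
and 67 DZ pairs (380 subjects), 48 areas in two hemispheres, 4 runs of
1200 time points split over two session days — with simple, stated
distributions where the empirical ones are not published:

* ages uniform 22–36 y, identical within a pair; sex shared within MZ
  pairs; reconstruction version shared within a pair; mean framewise
  displacement log-normal (median 0.12 mm, log-sd 0.35), independent
  across co-twins. The FD distribution and its effect size are not
  published; these defaults are plausible for a young-adult cohort and are
  stated, not derived.
* covariate effects on Fisher z: age −0.002/yr, sex 0.02, mean FD
  −0.10/mm, reconstruction 0.01; phenotype variance of z given covariates
  0.03 (sd ≈ 0.17).
* generative curve `h_max = 0.5, a1 = 0.3, b1 = 1.2, a2 = 0.005,
  b2 = 0.4`: non-monotonic with its maximum near `eta = 3` (the lower
  third of the fixture's 0–10 level range), a strong early rise, and
  values within (0.19, 0.48) across the whole hierarchy. A maximum much
  earlier than this is incompatible with keeping the curve positive at the
  top of a 10-level hierarchy for any appreciable long-term amplitude.
* a connection's true heritability is the mean of the curve at its two
  endpoint levels. Under this rule the noiseless per-area average is an
  affine function of the curve at the area's own level (amplitude halved
  once), so the aggregated profile keeps the curve's shape; assigning the
  curve at the mean endpoint level instead smooths twice and crushes the
  profile amplitude.
* mean Fisher z per connection decays with graph distance,
  `0.4 exp(-0.2 d) + 0.05`.
* session-day replicates are `z ± u` with anti-correlated day noise, so
  the two-day average equals the subject value exactly (the generative
  heritability curve is preserved) while the day-to-day ICC follows the
  target profile `0.8 - 0.25 exp(-0.8 eta)` — increasing with level, as
  expected if transient fluctuations shrink up the hierarchy. Real session
  noise is independent across days and attenuates heritability; the
  anti-correlated construction trades that realism for exact control of
  both profiles at once.
* anatomical phenotypes (thickness- and volume-like) have true
  heritability declining linearly with level (0.60 − 0.040 eta and
  0.65 − 0.045 eta, floored at 0.05), covariate effects age −0.005 and
  sex 0.10.

Time series are multivariate Gaussian with the population correlation
matrix equal to the nearest positive-definite repair (eigenvalue clipping
at 1e−6, rescaled to unit diagonal) of `tanh(z)`; subjects whose repair
moves the matrix by more than a stated relative Frobenius distance (0.1)
are flagged as non-embeddable. Because per-connection phenotypes are drawn
independently, assembled target matrices are occasionally slightly
indefinite; the repair handles this deterministically. The generator makes
no attempt at physiological noise, drift, or spatial autocorrelation —
Gaussian processes carry all the statistical structure the pipeline tests.

What passing tests on these conditions show: the estimators are unbiased
and calibrated under the stated covariance model, the screening respects
family structure, and the gradient models detect (and do not hallucinate)
curvature at the study's sample size. What they do not show: robustness to
non-Gaussian fMRI artifacts, atlas misfit, or empirical FD distributions —
those would need real data.

## Numerical choices and degenerate inputs

* AE likelihood evaluated family-block-wise; `h2` maximization bracketed
  on a 0.05 grid then refined; boundary estimates snapped when the
  boundary log-likelihood ties the interior optimum within 1e-10.
* LRT statistics are clamped at 0; negative values beyond numerical
  tolerance raise an error in `mixture_lrt_pvalue`.
* a numerically perfect quadratic (RSS at rounding level relative to the
  linear fit) reports `F = Inf, p = 0` rather than a meaningless ratio.
* intercept-only component fits floor the RSS at 1e-20 so a perfect fit
  yields a very negative finite AIC instead of `-Inf`.
* duplicate ROI series (`|r| = 1`), zero-variance columns, constant
  phenotypes, 3-member families, self-loops, unreachable areas, and empty
  p-value vectors all raise named errors at the stage that first sees
  them.

## Problem sizes used by the test suite

The statistical tests run at the study's cohort size (123 + 67 pairs).
Recovery uses 200 replicates per heritability level, null calibration of
the LRT 1000 replicates, the sign-flip screen 500 replicates at 199
permutations, the two-component noise study 100 seeds at noise sd 0.03
and component attribution 200 seeds, and the curvature detection study 50
seeds per generative profile on one 24-area hemisphere. Oracle-equivalence
checks run 30 random instances per statistic against brute-force
reimplementations. These sizes keep Monte-Carlo error well below the
asserted tolerances.

## Known limitations

* Twin pairs only: no extended pedigrees, no multi-level permutation
  block trees, no dominance or shared-environment components.
* The AE engine matches SOLAR-style variance-components ML at the level
  of the stated likelihood; no attempt is made to reproduce any specific
  package's parameterization or priors.
* The packaged adjacency is a synthetic stand-in; hierarchical levels on
  real data require the real atlas adjacency.
* `h_max` is fixed, not estimated; misspecifying it biases the component
  amplitudes though not the presence of non-monotonicity.
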