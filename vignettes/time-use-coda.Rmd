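---
title: "Compositional analysis of 24-hour time use: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour time use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codatime)
```

## The model

A day of D mutually exclusive, exhaustive behaviours is a composition
`x = (x_1, …, x_D)`, `x_j > 0`, closed to a total T (1440 min). Only the
ratios `x_j / x_k` are informative: rescaling a row changes nothing
("scale invariance"), and the sample space is the simplex, where the
natural operations are perturbation (componentwise product, then closure)
and powering (componentwise power, then closure), not addition and
scalar multiplication.

`codatime` works throughout in logratio coordinates. The centred logratio
`clr_j(x) = ln(x_j / g(x))`, with `g` the geometric mean, embeds the
simplex isometrically in the sum-zero hyperplane of R^D; the pivot
(isometric logratio) coordinates

```
z_k = sqrt((D−k)/(D−k+1)) · ln( x_(k) / ( Π_{j>k} x_(j) )^{1/(D−k)} ),  k = 1, …, D−1
```

are an orthonormal parameterisation of that hyperplane in which the
first coordinate contrasts a chosen *pivot* part against the geometric
mean of all the others. The normalising constants follow the standard
pivot-coordinate convention so coefficients are comparable with the
published CoDA literature; the source material we calibrate against
delegates the formula to its references, and we adopt this standard form.
`z_1` depends only on *which* part is the pivot; `z_2, …` additionally
depend on the order of the non-pivot parts, which `codatime` fixes to the
stored column order (documented because any such order gives the same
model space).

Descriptives follow from the same geometry: the compositional center is
the closure of the per-part geometric means (it minimises mean squared
Aitchison distance, the Euclidean distance between clr vectors); the
variation array collects `var(ln(x_j/x_k))` above the diagonal and
`mean(ln(x_j/x_k))` below it, and the identity
`mean(ln(x_j/x_k)) = ln(center_j / center_k)` is exact.

The outcome model is ordinary least squares,

```
y = β0 + β_z' z + γ' w + ε,    ε ~ N(0, σ²),
```

with `z` the pivot coordinates and `w` untransformed covariates. Every
pivot choice spans the same column space, so fitted values, residuals, R²
and the global composition test (the nested F test of all D−1
coordinates) are pivot-invariant; the per-part table reports, for each
part, the first coordinate of the fit in which that part is the pivot
("part vs Remaining"). These are D views of one model, so no multiplicity
adjustment is applied across rows.

Isotemporal substitution converts coefficients into minutes: moving `m`
minutes between behaviours at a reference composition changes the
coordinates by `Δz`, and the predicted outcome difference is
`Δ = Δz' β_z` with variance `Δz' Cov(β_z) Δz` — covariate terms cancel in
the difference. The map from minutes to coordinates is logarithmic, so
dose-response curves are straight in coordinates but asymptotic in
minutes, and reallocating +m versus −m minutes is asymmetric except in
the `m → 0` limit. Predictions diverge as any part approaches zero; the
package refuses infeasible reallocations rather than returning NaN.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| closure total | 1440 | min/day | display-only: internals use proportions |
| ingestion row-sum tolerance | 1% | relative | diary rounding is renormalised; worse is rejected as a data error |
| zero-replacement fraction | 0.65 | of detection limit | common simple-replacement practice |
| detection limit | 1 | min | a diary's time resolution; configurable per part |
| CI level | 0.95 | — | t-based, residual df |
| substitution grid | ±120 by 5 | min | two hours spans the reallocations usually discussed |
| surface margin | 1% | of total per part | keeps the grid out of the divergence zone near edges |
| predictive-region quantile | chi-square, D−1 df | — | large-n form; the F-based small-sample scaling is a known refinement not used by default |

## The synthetic-cohort generator

The generator emulates a three-part (Sleep, SB, PA) child cohort.
Defaults: center (617.5, 553.1, 269.4) min/day; pairwise logratio
variances 0.13 (Sleep–SB), 0.39 (Sleep–PA), 0.78 (SB–PA); per-part
"vs Remaining" effects on a zBMI-like outcome of (−0.21, +0.19, +0.02);
age ~ N(10.9, 0.3²), sex ~ Bernoulli(0.5), socioeconomic position
~ N(0, 1), with null covariate effects by default; n = 3228.

Pivot coordinates are drawn multivariate-normal with mean at the center's
coordinates and covariance `V Σ V'`, where `Σ = −½ G T G` double-centres
the variation matrix `T` (`G = I − 11'/D`) and `V` is the pivot contrast
matrix; compositions are the inverse-pivot images, strictly positive by
construction. This is exactly the logratio-normal model that the
predictive-region code fits, so region coverage can be checked against
its nominal level.

The D per-part pivot effects are not free parameters: they are rotated
views of a single linear functional `b' clr(x)`, with
`β_l = sqrt(D/(D−1)) b_l`, which forces `Σ β_l = 0`. The default effects
satisfy this exactly, and the generator validates it for user-supplied
values.

Two calibration choices were open and are the package's own:

* **Residual SD.** No residual SD accompanies the published effect sizes.
  We set `σ` analytically so that the expected global composition F at
  n = 3228 is ≈ 4 given the default variation and effects
  (`σ² = n · Var(b' clr(x)) / 6`, giving σ ≈ 1.177). A useful coherence
  check: the coefficient standard errors this implies (0.122, 0.086,
  0.050) are close to the published ones (0.11, 0.07, 0.05), so the
  calibration reproduces both the effect sizes and their uncertainty at
  the published cohort size.
* **Covariate effects** default to zero because no values are published;
  they exist so adjustment machinery is exercised, not to add signal.

What the generator does *not* emulate: diary measurement error,
day-of-week and seasonal structure, within-child longitudinal
correlation, and rounded zeros (compositions are strictly positive by
construction; an explicit `inject_zeros()` step creates them for testing
the replacement pipeline). Passing tests therefore demonstrate the
correctness of the geometry, the estimators and their calibration under
the logratio-normal ideal — not robustness to the messiness of real
diary data.

## Numerical choices and degenerate inputs

* Natural logs everywhere.
* Aitchison distance uses the clr-Euclidean convention with no extra
  `1/sqrt(D)` factor (a pairwise-logratio convention with that factor
  also circulates; ours matches the isometry with pivot coordinates).
* The change index normalises by the in-sample maximum distance, so the
  farthest participant scores exactly 1; the normaliser is configurable
  because cross-sample comparisons need a fixed one. The choice of
  normaliser is an implementation decision — the descriptive source we
  mirror does not state one.
* Variances use denominator n − 1.
* `inverse_pivot` subtracts the row maximum before exponentiating, so
  coordinates as extreme as `z_1 = 30` back-transform to a composition
  with essentially the whole day in the pivot part instead of
  overflowing.
* Sums are renormalised exactly at closure, so row totals are preserved
  to machine precision through zero replacement and reallocation.
* Rank-deficient regression designs, singular coordinate covariances,
  all-zero rows, infeasible zero replacements (δ ≥ row total) and
  infeasible reallocations (a part driven ≤ 0) raise errors naming the
  offending column or part; nothing silently returns NaN.
* Ternary corners default to (left, right, top) = stored part order,
  i.e. (Sleep, SB, PA) for the default cohort, and are configurable.

## Problem sizes used in the test suite

Property tests run on 1000 random compositions (isometry), 200 simulated
cohorts of n = 3228 (coefficient recovery and CI coverage), one cohort of
n = 10,000 (predictive-region coverage) and one of n = 50,000
(moment convergence of the generator). These sizes put Monte-Carlo error
well inside the asserted tolerances while keeping the full suite in the
tens of seconds on one CPU.

## Known limitations

* Only continuous outcomes (OLS); no logistic, survival or multivariate
  outcome models, and no regression with the composition as the response.
* Simple multiplicative zero replacement only; model-based (lognormal/EM)
  imputation and essential-zero strategies are out of scope — essential
  zeros are flagged, never imputed, and amalgamation is the supported
  workaround.
* Pivot bases only; arbitrary sequential binary partitions or
  user-defined balance trees are not provided.
* The CLI writes plot-ready CSV coordinates (ternary points, region
  boundaries, surfaces) but does not render images.
* Predictive-region boundaries are traced for three parts only (for
  D > 3 the fitted mean/covariance are still available).
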