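# codatime

Compositional data analysis (CoDA) for 24-hour time-use epidemiology.

Daily activity behaviours — sleep, sedentary behaviour (SB) and physical
activity (PA) — are mutually exclusive and exhaustive parts of a fixed
24-h day. Minutes spent in one behaviour can only come from the others, so
the data carry *relative* information: their sample space is the simplex,
not real space, and standard "absolute" statistics (arithmetic means,
Euclidean distances, raw-minute regressions) are geometrically wrong for
them. `codatime` is for epidemiologists and movement-behaviour researchers
who want to analyse such data in the Aitchison geometry and interpret the
results back in minutes per day.

## What it does

For a composition `x = (x_1, …, x_D)` with `x_j > 0` closed to a total
(1440 min/day):

* **Simplex operations** — closure `C(x) = (x_1, …, x_D) · T / Σx_j`,
  perturbation `x ⊕ p = C(x_1 p_1, …, x_D p_D)` and powering
  `a ⊙ x = C(x_1^a, …, x_D^a)`, plus amalgamation of parts.
* **Logratio transforms** — centred logratio `clr_j = ln(x_j / g(x))`;
  additive logratio; and pivot (isometric) coordinates
  `z_k = sqrt((D−k)/(D−k+1)) · ln( x_(k) / gm(x_(k+1), …, x_(D)) )`,
  whose first coordinate isolates one part against the geometric mean of
  the rest ("Sleep vs Remaining"), with exact inverses.
* **Descriptives** — the compositional center (closed geometric means),
  the variation array (pairwise logratio variances and means), Aitchison
  distance, a normalised change index, logratio-normal predictive regions
  and ternary plotting coordinates.
* **Rounded zeros** — detection and multiplicative simple replacement
  (`delta = 0.65 × detection limit`, other parts scaled so the row total
  and their mutual ratios are preserved exactly).
* **Regression** — OLS of a continuous outcome (e.g. zBMI) on pivot
  coordinates plus covariates; a per-part "vs Remaining" coefficient
  table; a global composition F test. All of these are invariant to the
  pivot choice and to the measurement scale (minutes vs hours).
* **Isotemporal substitution** — model-based predicted outcome differences
  for reallocating time between behaviours (one-to-one or
  one-for-remaining), with t-based confidence intervals, dose-response
  curves and ternary response surfaces. Because the coordinate-to-minutes
  map is non-linear, adding and removing the same duration give
  asymmetric estimates.
* **Synthetic cohorts** — a logratio-normal generator calibrated to a
  three-part child cohort (center 617.5/553.1/269.4 min/day; logratio
  variances 0.13/0.39/0.78; pivot effects −0.21/0.19/0.02 on zBMI), so
  every stage is testable without restricted cohort data.
* **CLI** — `describe`, `regress`, `reallocate`, `surface` and `simulate`
  subcommands over cohort CSV files (see `inst/cli/codatime.R`).

## Worked example

```r
library(codatime)

# a synthetic cohort at the calibrated defaults (n = 3228)
d <- generate_cohort(generator_config(), seed = 7)

va <- variation_array(d)
round(variation_table(va), 2)
#>       Sleep    SB   PA center
#> Sleep    NA  0.13 0.39 617.84
#> SB    -0.11    NA 0.77 553.92
#> PA    -0.83 -0.73   NA 268.24

pivot_table(d, covariates = c("age", "sex", "sep"))
#>                pivot    estimate         se         t          p
#> 1 Sleep vs Remaining -0.07367534 0.12247644 -0.601547 0.54751801
#> 2    SB vs Remaining  0.14598507 0.08736048  1.671065 0.09480587
#> 3    PA vs Remaining -0.07230973 0.04978948 -1.452309 0.14651299

fit <- fit_composition_model(d, covariates = c("age", "sex", "sep"))
ctr <- compositional_center(d)
substitution_estimate(fit, ctr, reallocation("PA", "SB", 120))
#> <substitution: +120 min to PA from SB>
#>   delta = -0.051  [-0.081, -0.021] (95% CI)
```

Read: the variation array's upper triangle says most pairwise variability
is between PA and SB (0.77); its lower triangle says PA is on average
`exp(-0.83) = 0.43` times Sleep. The pivot table views one fitted model
three ways — each row is the first coordinate when that part is the pivot;
in this particular draw no single pivot reaches 0.05, yet reallocating two
hours from SB to PA at the cohort center still predicts a 0.05 lower zBMI
with a CI excluding zero, because the substitution contrast pools the
coordinate effects.

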