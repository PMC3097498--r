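---
title: "Factorial optimization of forced degradation: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial optimization of forced degradation: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdopt)
```

## The problem and the model

Stress testing a drug substance needs settings (here: alkali strength,
microwave irradiation time, microwave power) that produce a moderate,
controlled amount of degradation. `fdopt` treats this as a two-level
full factorial problem. Each factor is coded to ±1 by the
midpoint/half-range transform, and the `2^k` runs support the saturated
polynomial

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j + \dots$$

**Assumptions.** Responses are the polynomial surface plus i.i.d. noise;
each factor acts linearly between its two levels (two levels cannot
detect curvature); runs are independent. The saturated fit has zero
residual degrees of freedom, so it interpolates the data exactly —
goodness of fit is *not* evidence here, which is why significance
screening needs a pooled error term.

**Estimation.** With ±1 coding the model-term columns are mutually
orthogonal, so each coefficient is the contrast average
$\beta_T = \frac{1}{2^k}\sum_{\text{runs}} \big(\prod_{i \in T} x_i\big) y$.
The package computes this directly and also ships the classical Yates
pairwise sum/difference algorithm (`yates_algorithm()`); the test suite
verifies algebraic agreement of the contrast, Yates and dense
least-squares routes on random designs for $k = 2\ldots5$.

## Significance screening on an unreplicated design

An unreplicated factorial has no pure-error estimate, so
`screen_effects()` pools presumed-inert terms into an error mean square
and tests each remaining term with $F = SS/MS_{pool}$ on $(1, |pool|)$
degrees of freedom.

*Default pool* (a genuinely open design choice): all interactions of
order ≥ 2 whose absolute effect is **not** in the top half of all
non-intercept effects. Rationale: effect sparsity/heredity — large
effects and main effects are the plausible signals; small high-order
interactions are the conventional noise proxy. The default is a
heuristic, not an inference guarantee: with only a handful of pooled
terms the F test is fragile, and a single active interaction in the pool
inflates the error term. Every report states the pool used, and `pool`
can be set explicitly. Worked examples in the documentation use the
three smallest interactions of the bundled experiment. We deliberately
assert only the significance *ordering* of factors in tests, never
specific F values, because the screen's absolute numbers depend on the
pooling convention.

`alpha` defaults to 0.05 everywhere.

## Model reduction and closed-form inversion

Dropping a factor removes every term containing it while leaving the
other coefficients untouched — exact under orthogonality (a
least-squares refit of the reduced term set returns identical values;
this is also what substituting the dropped factor's coded value 0 into
the full equation does). The reduced model keeps the full factor list so
decoding still works.

The fitted polynomial is linear in any single coded coordinate once the
others are fixed. `solve_for_factor()` therefore inverts it exactly:

$$x_s = \frac{Y^* - A}{B}, \qquad
A = \text{terms without } s \text{ at the fixed coordinates}, \quad
B = \sum_{T \ni s} \beta_T \prod_{i \in T\setminus s} x_i .$$

Numerical choices: the denominator is declared degenerate below
`1e-12` (contour parallel to the axis → explicit no-solution error, and
flagged-but-kept rows in `contour_grid()`); every solution is
back-substituted through `predict()` and must match the target within
`1e-9` absolute — an internal assertion, not a user tolerance.
`recommend_conditions()` refuses solutions outside the coded cube
$[-1,1]^k$ unless extrapolation is explicitly allowed, because nothing
supports the model outside the design region. Two defaults the package
had to choose: unfixed, unsolved factors sit at the design centre
(coded 0, the least-assuming point), and when no solve factor is named
the free factor with the largest absolute main-effect coefficient is
used — it is the strongest lever, giving the smallest coded excursion
for a given target.

## Validation statistics

- Calibration: ordinary least squares of area on concentration
  (`stats::lm` under the hood), $r^2$ as squared Pearson correlation.
- `%RSD`: $100 \cdot s/\bar{x}$ with the sample ($n-1$) standard
  deviation — the convention that matches published recovery tables
  (the population form would disagree visibly).
- Intermediate precision: balanced one-way ANOVA with **days as
  groups**, $F = BMS/WMS$ compared with `qf(1 - alpha, d-1, d(r-1))`.
  The critical value is always computed from the quantile function, not
  a printed table. `WMS = 0` yields an *undefined* F (reported `NA`,
  never `Inf`) and an indeterminate verdict.

Display convention: human-readable reports round half-to-even at two
decimals; machine-readable JSON/CSV carry full precision. Published
tables of this kind are sometimes *truncated* rather than rounded at two
decimals; comparisons against such tables should allow one display ulp
(the test suite does).

## What the synthetic generators emulate — and what they don't

`simulate_factorial_responses()` draws $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$ i.i.d.;
`simulate_recovery_panel()` draws the one-way random-effects layout
$y_{dr} = \mu + B_d + e_{dr}$; `simulate_calibration()` draws a straight
line plus Gaussian area noise (defaults: slope 601211, intercept 41127
over 0.5–5 µg/mL, a realistic HPLC-UV response for this analyte class).
All generators are deterministic given a seed and restore the caller's
RNG state.

Gaussian noise is a modelling choice, made once: no error model is
stated for such experiments, homoscedastic normal errors are what the
contrast/ANOVA theory assumes, and it makes the calibration targets
(RMSE $\approx \sigma/\sqrt{2^k}$ per coefficient, type-I error
$\approx \alpha$ for the precision F test) exact sampling-theory
statements. Consequences: simulated degradation can go negative under
large noise (clipping at zero exists behind `clip_at_zero` but is off by
default, since the statistical checks assume unclipped normals), and
real chromatographic error features — heteroscedasticity across
concentration, day-level drift correlated with run order, integration
outliers — are *not* emulated. A green simulation-based test therefore
establishes internal statistical correctness of the pipeline, not
robustness of a laboratory method.

## Known limitations

- Full factorials only: no fractional designs, blocking, centre points
  or response-surface designs; two levels per factor cannot estimate
  curvature, so interpolated settings (e.g. a mid-range power
  recommendation) assume linearity between levels.
- The pooled-error F screen is heuristic on unreplicated designs (see
  above); half-normal/Lenth-style alternatives are out of scope.
- Calibration reports linearity only — no LOD/LOQ, weighting, or
  lack-of-fit with replicates.
- `k` is capped at 10 (1024 runs) to guard against accidental
  exponential blow-up.
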