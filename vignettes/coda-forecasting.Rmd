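---
title: "Forecasting compositional age structures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting compositional age structures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codaf)
```

## The problem and the model

An annual population age structure is a point on the 2-simplex: the
young, middle-aged and old shares are nonnegative and sum to one. Treating
the three shares as unrelated real-valued series invites forecasts that
violate both constraints, and Euclidean error measures misrepresent how
far apart two structures really are (a move from 2% to 4% old-age share is
a doubling; a move from 50% to 52% is not). `codaf` therefore works in
Aitchison geometry: compositions are compared by the distance between
their centred log-ratio (clr) images, and forecasting happens in
unconstrained coordinate systems that map back onto the simplex.

The pipeline has three stages. First, a transform removes the unit-sum
constraint: LCC drops one component and models the rest directly, ILR maps
to `D−1` orthonormal log-ratio coordinates, DRHT writes the square-root
composition in hyperspherical angles. Second, a standard time-series model
(ARIMA, exponential smoothing, VAR, or a neural autoregression) forecasts
each coordinate. Third, the inverse transform produces composition
forecasts. Candidate transform–model pairs are compared on a held-out
span of the series by CoDa-RMSE (mean Aitchison distance) and CoDa-MAPE
(the same, normalised by each observation's Aitchison norm), the winner's
residuals are screened with Box–Pierce and Ljung–Box portmanteau tests,
and the winner is refit on the full series for the future horizon.

Assumptions worth stating: the series is annual, gap-free and strictly
inside the simplex (zeros are repaired, ones are not); the secular change
is smooth enough that a linear-family model on log-ratio coordinates can
track it; and model selection by a 48/9-style split assumes the test span
is representative of the near future.

## Tunable parameters

- `epsilon` (default `1e-6`, proportion units): multiplicative zero
  replacement before any log-ratio operation — zero parts are set to
  `epsilon`, the rest scaled down proportionally, the row re-closed. Also
  the lower clip bound when an invalid (off-simplex) forecast row must be
  repaired for metric computation. The default is far below any plausible
  annual share, so it never distorts regular data.
- ARIMA: automatic order search over `p ≤ 3, d ≤ 2, q ≤ 3` by corrected
  AIC, with a drift regressor when `d = 1` (without it, differenced models
  forecast flat and systematically miss secular demographic trends).
  Fixed orders via `model_config(arima_order = c(p, d, q))`.
- ETS: candidates are simple and trend-corrected (Holt) additive
  exponential smoothing, chosen by corrected AIC computed from the
  one-step errors; `ets_form` forces either.
- VAR: least-squares with intercept, lag order by a per-equation Gaussian
  AIC up to `var_max_lag` (default 5). The per-equation criterion (sum of
  log equation variances) replaces `log det Σ` because jointly fitted
  unit-sum series have an exactly singular residual covariance;
  collinear regressors are dropped via pivoted QR, which is equivalent to
  fitting the reduced system.
- NNETTS: `m` lagged inputs, `hidden` units, logistic activation, linear
  output, trained by least squares on the standardised series with
  `restarts = 20` seeded initialisations (weights uniform in (−0.5, 0.5));
  the lowest in-sample loss wins, so results are deterministic in
  `(series, m, hidden, restarts, seed)`. Multi-step forecasts iterate the
  one-step map recursively. `nnetts_select()` tunes `(m, hidden)` over a
  3 × 5 grid by the same out-of-sample CoDa-RMSE criterion used for the
  main comparison.
- Diagnostics: `lags` defaults to `min(10, floor(n/5))` usable residuals
  per component.
- Forecast horizon: default 18 years beyond the last observation.
- Default seed `20190411`; every stochastic routine takes an explicit
  seed.

## Numerical choices and degenerate inputs

- **ILR inverse.** The clr expansion of the pivot coordinates sums to
  zero by construction, so the inverse is the softmax
  `x_d = exp(v_d) / Σ exp(v_i)` (computed with a max-shift against
  overflow). A "normalise by `Σ v_d`" reading of the inverse is degenerate
  — it divides by zero for every input — and is ruled out by requiring
  `ilr_inverse(ilr_forward(x)) = x`, which the test suite checks to
  `1e-10` over random compositions in dimensions 2–6.
- **DRHT operates on square roots.** The angles are spherical coordinates
  of `y_d = √x_d` (so `Σ y² = 1`); taking `arccos` of raw shares would
  not invert against the squared-cosine back-map. `arccos` arguments are
  clamped to `[0, 1]` for numerical safety. When the running sine product
  underflows (`< 1e-12`, i.e. no mass remains for the leading parts) the
  remaining angles are set to 0 — any value reproduces the same
  composition, the convention only fixes the representation.
- **Forecasted angles** outside `[0, π/2]` are clipped to the boundary
  with a warning; the clamp count is reported in forecasts and grid
  entries.
- **CoDa-RMSE is a mean of distances**, not a root mean square; that is
  how the measure is conventionally defined for compositions, and the
  name is kept for recognisability. `root_mean_square = TRUE` gives the
  true RMS variant.
- **Invalid LCC (and raw-scale) forecast rows** keep their raw values and
  a `valid = FALSE` flag in the forecast object; only at metric time are
  they clipped to `[epsilon, 1]` and re-closed, with the repair count in
  the report. Repairing in place would hide exactly the pathology the
  flags exist to expose.
- **"Base" runs** fit each raw share series directly (VAR: all shares
  jointly) and re-close the forecasts, giving the untransformed baseline
  that the transforms must beat.
- **Residual diagnostics** are computed on the original proportion scale
  (observed minus back-transformed fitted share, per component), so the
  same three-component table applies to every transform.
- **Selection tie-breaks** are fixed and documented: CoDa-RMSE, then
  CoDa-MAPE, then transform order ILR < DRHT < LCC.Y < LCC.M < LCC.O <
  Base, then model order ARIMA < ETS < VAR < NNETTS. An
  `exclude_transforms` filter supports restricting the winner to
  simplex-respecting transforms: an LCC cell can win the raw numbers
  while producing flagged forecasts, which some users reasonably refuse —
  the bundled `benchmark_grid("vietnam")` is exactly such a case.
- **Component order is a convention**: young/middle/old = 1/2/3. ILR and
  DRHT coordinates depend on it; it is recorded in all outputs.
- The train/test boundary is a calendar year, not an index, so series
  with missing years fail loudly instead of silently shifting the split.

## The synthetic generator

`simulate_coda_series()` draws ILR coordinates along a linear trend with
AR(1) noise, `w_t = a + b·t + e_t`, `e_t = φ e_{t−1} + ε_t`,
`ε_t ~ N(0, σ²)`, and back-transforms. The defaults (three parts, 57
years, `φ = 0.5`, `σ = 0.05` log-ratio units) emulate the length and
serial dependence of published national age-share series; the three
presets pin the trend by stylised start and end compositions (e.g.
`china-like`: young 40%→18%, old 4%→10% over 57 years). The AR(1) state
starts at 0 rather than the stationary distribution so that short series
are exactly seed-reproducible; for `φ = 0.5` the difference is immaterial
after a handful of years.

A linear ILR trend was chosen because log-ratio-linear models are the
strongest performers in this class of pipeline, giving the generator a
known analytic continuation to test forecasts against
(`ilr_inverse(a + b·t)` with `σ = 0`). What the generator does **not**
emulate: structural breaks (policy shocks, wars, migration waves),
age-heaping and census revisions, nonlinearity in log-ratio space, or
cohort dynamics — it is scaffolding with known ground truth, not a
demographic model. Tests passing on it show the machinery is correct,
not that any particular country's future is predicted well.
`recover_parameters()` closes the loop: OLS per coordinate recovers
`(a, b)` and a conditional least-squares step `(φ, σ)`, exactly for
noiseless input.

## Problem sizes used in the test suite

Round-trip, isometry and metric-axiom properties run on 1,000 random
compositions (dimensions 2–6). Portmanteau calibration uses 1,000
replicates of iid normal residuals (n = 100, 10 lags), with the type-I
band 0.05 ± 0.02 read inclusively; the power check uses 200 AR(0.9)
replicates. Slope recovery averages 200 replicates at the preset noise
level. The end-to-end run uses the three presets at full study scale
(57 years, 48/9 split, all 24 grid cells, and the 3 × 5 NNETTS sub-grid),
plus a bitwise-reproducibility re-run on one preset. These sizes keep the
whole suite under two minutes on one CPU while leaving every property
statistically meaningful.

## Known limitations

- ARIMA orders are searched independently per coordinate; no seasonal
  terms (annual data).
- The ETS family is additive-error simple/Holt smoothing; damped-trend
  and multiplicative variants are not offered.
- NNETTS least-squares training is non-convex; determinism comes from
  seeded restarts, and the found optimum may still be local. On 48-point
  training windows the network is deliberately tiny (`m ≤ 3`,
  `hidden ≤ 5`).
- A share of exactly 1 (a degenerate composition) is outside every
  transform's domain and is rejected rather than repaired.
- Forecast uncertainty is not quantified: the pipeline produces point
  forecasts, and the portmanteau screen is a necessary, not sufficient,
  adequacy check.
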