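---
title: "Modelling daily litter moisture content: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily litter moisture content: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littermoist)
```

## The problem

Daily forest fire danger forecasts hinge on the moisture content of surface
dead fuels. The litter moisture content (LMC) — water mass as a percentage
of oven-dry mass, `M = 100 (W_wet - W_dry) / W_dry` — controls how easily
leaf litter ignites; the daily minimum, reached around 14:00, is the
conservative quantity a fire manager wants predicted. Because gravimetric
measurement (destructive sampling and oven drying) cannot give a same-day
value, LMC must be modelled from weather. `littermoist` implements three
model families used operationally for this task, an evaluation and
cross-site extrapolation protocol, and a synthetic data generator that
emulates a subtropical-plateau dry season so every stage can be exercised
and tested without field data.

Analysis is restricted to fire-relevant days: litter above roughly 35 %
moisture will not carry fire, so `filter_below_threshold()` keeps only
days with LMC strictly below the threshold. Whether the boundary itself is
kept is a modelling decision, not an empirical fact; we chose strict `<`
(a day at exactly 35.0 % is excluded) and made the threshold an argument.

## Lagged predictors and correlation profiles

Litter responds to weather with a lag, so the regression predictors are
windowed statistics anchored at the 14:00 sampling time
(`lagged_features()`): for lag `n >= 1` the window is the trailing
`n * 24` h ending at 14:00 of the sampling day — mean temperature `T_n`,
mean relative humidity `H_n`, mean wind `W_n`, accumulated rainfall `R_n`
— and for `n = 0` the same-day 00:00–14:00 window. Two conventions were
genuinely open: whether "n days ago" includes the sampling day, and what
the `n = 0` window means. We use trailing windows that *end* at the
anchor (so lag 1 includes the preceding 24 h) and a same-day partial
window for lag 0, which keeps lag 0 a quantity knowable at sampling time.
Windows are scored by coverage (records present over records expected from
the series' median time step); features with coverage below 0.8 are set to
`NA` rather than computed from a partial window, a guard the source data
never needed but real station records do.

`spearman_lag_profile()` gives the rank correlation (mid-ranks for ties)
between LMC and each element across lags 0–10, with exact small-sample
p-values (n ≤ 10, tie-free) and the t approximation otherwise. All-tied
windows are flagged `defined = FALSE` instead of propagating `NaN`.

## Model 1: stepwise meteorological regression

`fit_stepwise()` selects predictors for the linear model
`M = b0 + sum(b_i X_i)` from the 44 lagged candidates by forward entry and
backward removal on partial-F p-values (enter at 0.05, remove above 0.10,
the classical thresholds). One refinement matters: at each entry step the
smallest candidate p-value is compared against `p_enter / m`, where `m` is
the number of candidates examined (a Bonferroni adjustment). Without it,
screening 44 candidates at a raw 0.05 admits at least one pure-noise
predictor in most datasets; with it, the per-step false-entry probability
stays near 5 % regardless of pool size, a pure-noise response usually
yields the intercept-only model, and a single true predictor is selected
alone. Candidates whose variance inflation factor against the current
model exceeds 10 are skipped, so the final equation carries no serious
multicollinearity. Ties break by the fixed candidate order (T, H, W, R,
ascending lag), making selection deterministic and row-order invariant.

## Model 2: moisture-code (FFMC) methods

The fine fuel moisture code F (0–101) of the Canadian Fire Weather Index
System tracks fine dead fuel dryness from daily temperature, humidity,
wind and rain. `ffmc_daily()` implements the standard daily update
(rainfall wetting above the 0.5 mm trap with the high-moisture absorption
term and 250 % cap; log drying/wetting toward the humidity- and
temperature-driven equilibria), using 147.27 as the code↔moisture
conversion constant throughout so the conversion pair is an exact
bijection. Since the originating study used F values without printing the
update equations, externally computed FFMC series can be supplied via
`read_ffmc()`. Start-up is F = 85 with a 3-day spin-up flag, both
configurable; station winds in m/s are converted to km/h. Daily inputs are
taken at the 14:00 anchor (the closest record), consistent with the
sampling time, rather than the FWI System's nominal noon observation.

Two algebraic scale models convert F to a moisture percentage:
FF `147.27 (101 - F) / (59.5 + F)` and FX `32.87 (101 - F) / (13.28 + F)`
(the FX calibration targets hot, dry regions). Used directly, both are
first screened by a paired t-test (`applicability_ttest()`): a significant
measured-vs-predicted difference means the raw scale model is not usable.
The fallback is the moisture-code regression `M = alpha * M_scale^beta`
(`fit_mcode_regression()`), fitted as a line on natural-log-transformed
data because the variance of measured LMC grows with its level. No
retransformation (smearing) correction is applied to the back-transformed
power law — the plain form is the model.

## Model 3: direct estimation (Nelson EMC + diffusion)

The semiphysical direct estimation method drives litter moisture toward
the Nelson equilibrium moisture content

`E = alpha + beta * ln( -(R T / m) ln H )`,

with `R = 8.314` J/(K mol), `m = 18.0153` g/mol, temperature in Kelvin and
humidity as a fraction, through the discretized water-diffusion recursion

`M_i = lambda^2 M_{i-1} + lambda (1 - lambda) E_{i-1} + (1 - lambda) E_i`.

Three numerical decisions:

* The continuous form is printed in the source literature with a sign that
  would repel moisture from equilibrium; the discrete recursion is the
  internally consistent operational equation (its coefficients sum to one,
  making each prediction a convex combination), so the recursion is
  authoritative here.
* Humidity enters as a fraction clamped to [0.001, 0.999]; `ln` of a
  percentage above 1 would make the inner argument negative. Both
  logarithms are natural, the standard Nelson form.
* The recursion weight maps to the fuel's exponential time lag by
  `lambda = exp(-dt / (2 tau))` (trapezoidal discretization at step `dt`),
  i.e. `tau = -dt / (2 ln lambda)`. The packaged reference fits confirm
  this relation: all eight published (lambda, tau) pairs agree within the
  rounding of a two-decimal lambda (< 1.6 % relative).

`fit_direct()` minimizes the one-step-ahead squared error with teacher
forcing — each day is predicted from the *observed* previous-day moisture,
matching the operational setting where yesterday's measurement is
available — over days whose previous calendar day is observed. Days
removed by the 35 % filter break the chain and are simply excluded. `E` is
computed from the lag-1 daily mean temperature and humidity rather than
instantaneous 14:00 values (the averaging convention is configurable in
principle via the feature table; daily means are less noisy and match the
24 h step). Because the model is linear in `(alpha, beta)` for fixed
`lambda`, the optimizer profiles them out by ordinary least squares and
minimizes the one-dimensional profiled SSE over `lambda` on a 0.01 grid
followed by local refinement to tolerance 1e-10. This is equivalent to
bounded nonlinear least squares over all three parameters but is
deterministic, needs no starting values, and cannot fail to converge.
Degenerate inputs (constant `E` or constant moisture) leave `lambda`
unidentifiable and are flagged rather than silently fitted.
`predict_direct()` offers both the teacher-forced `one_step` mode and a
`free_run` mode recursing on its own predictions; under constant weather
the free run approaches equilibrium geometrically with ratio `lambda^2`.

## Synthetic data: what it emulates and what it does not

`generate_weather()` produces a seeded 30-min weather series matching, in
expectation, the dry-season regime of the reference campaign: mean daily
temperature 22.74 °C, mean relative humidity 37.18 %, mean wind 2.78 m/s,
rain on a minority of days averaging 1.34 mm. Where the campaign summary
gives no value, parameters were fixed once at field-plausible levels
implied by the published ranges: day-level anomaly SDs of 4.5 °C and 15 %
RH (consistent with daily means spanning roughly 9–32 °C and 15–92 % RH),
diurnal half-amplitudes of 6 °C and 12 % RH with the temperature peak at
14:00 and humidity in anti-phase, AR(1) day-to-day persistence 0.6,
gamma-distributed winds, and a 0.15 rain-day probability with exponential
daily totals. `simulate_moisture()` then runs the Nelson/diffusion forward
model (default truth `alpha = 30`, `beta = -5`, `lambda = 0.4`) on the
lag-1 daily means and adds truncated Gaussian observation noise (default
SD 1 %) *inside* the recursion, so each day evolves from the previous
observed value — exactly the error structure the teacher-forced fit
assumes.

The generator deliberately omits features of real litter beds: no
topographic or canopy modulation, no litter-bed structure effects, no
rain-interception physics beyond the weather series itself, and no regime
change between dry and wet seasons. Tests passing on synthetic data
therefore demonstrate the correctness of the algorithms and the internal
consistency of the fitting conventions — not field predictive skill.

With these defaults the equilibrium moisture sits near 5–6 %, so the
simulated litter is drier than the reference plots (means near 20 %); the
recovery tests care about parameter identifiability, not the absolute
level. Noise-free simulation recovers `(alpha, beta, lambda)` to 1e-4;
at 1 % noise over 100 days the median absolute error of `lambda` stays
within 0.05 across 50 replicate seeds (problem sizes chosen to exercise
the estimator thoroughly at sub-minute runtimes).

## Evaluation protocol

`error_metrics()` reports MAE, MRE (denominator = measured value, in
percent) and RMSE; `RMSE >= MAE` always. An MRE at or below 15 % is the
operational applicability rule (`applicability_verdict()`; the boundary
counts as a pass, the published rule stating only a "limit").
`cross_validate()` uses contiguous time folds — random folds would break
the previous-day structure of the direct model — with leave-one-out as the
default since "N-fold" leaves N open and per-plot samples are small.
`extrapolation_matrix()` fits per plot and evaluates on every other plot
(parameters from the source plot, features and measurements from the
target), summarizing off-diagonal cells by min/max/mean and the
coefficient of variation (sample SD over mean).

## Packaged reference values

`reference_table()` exposes machine-readable copies of the campaign's
published summary tables (weather regime, per-plot LMC statistics, raw
scale-model screening, and the fitted parameters and errors of all three
model families across the eight plots). They serve as fixtures: the
method-level mean errors recomputed from the per-plot values match the
published summary means (e.g. stepwise regression MAE 2.97 %, direct
estimation MAE 2.82 %), and the lambda–tau consistency check above runs on
them. One published summary value is arithmetically inconsistent with its
own per-plot column (the direct-estimation mean MRE, printed 12.76 %
against a column mean of 12.71 %) and is excluded from the fixture checks.
The per-plot parameter values themselves derive from raw field data not
shipped with the package and are treated as data, never as targets the
synthetic pipeline could or should reproduce.

## Known limitations

* The FFMC start-up value and the exact FFMC implementation used to
  produce any external F series are not knowable from published summaries;
  the external-F input path exists for that reason.
* The moisture-code regression's back-transformation is biased low for
  noisy data (no smearing correction), by design.
* Leave-one-out on a teacher-forced model still uses observed neighbours
  of held-out days; fold-level independence is weaker than for models
  without temporal state.
* The stepwise entry adjustment controls per-step, not experiment-wise,
  error; long candidate screens can still accumulate false entries over
  many steps.
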