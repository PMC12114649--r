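---
title: "Thermal-time phenology models with fall-winter residual correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time phenology models with fall-winter residual correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpgam)
```

## The problem

Temperate woody plants such as apricot flower in early spring once two
thermal requirements have been met: a fall-winter chilling requirement that
breaks endo-dormancy, and a spring forcing requirement -- an accumulation of
effective warmth -- that breaks eco-dormancy. Long phenological series
(year, observed first-flowering day-of-year) paired with daily temperature
records let both requirements be estimated statistically. `adpgam`
implements a two-stage analysis: a spring forcing model predicts the event
date from daily mean temperatures, and a generalized additive model (GAM)
of the forcing model's residuals on six fall-winter temperature (FWT)
summaries absorbs the systematic error that spring forcing alone cannot
explain.

## Stage one: forcing accumulation

All three forcing methods share one prediction kernel. Daily increments
$u_j \ge 0$ are accumulated from a starting day-of-year $S$; the predicted
event day is the first (fractional) day at which the running sum reaches a
mean annual requirement. When the running sum straddles the requirement
between days $F$ and $F+1$, the attainment day is interpolated linearly on
the cumulative curve (the trapezoid rule), so predictions are real numbers
and RMSEs are meaningful below one day. Predictions are never rounded
before the RMSE is computed.

**ADD (accumulated degree days).** The developmental rate is linear in
temperature, $r = a + bT$, zero below the biological zero
$T_0 = -a/b$. The annual requirement is
$k_i = \sum_{j=S}^{E_i} \max(T_{ij} - T_0,\, 0)$ with $E_i$ the observed
day; the mean $\bar k$ across years is the degree-day threshold. $S$ is
chosen first by the correlation protocol (`select_start_date_add()`): among
candidate starts, the one whose window-mean temperature is most strongly
anticorrelated (Pearson) with the observed dates. $T_0$ is then chosen by
grid search (default $[-5, 5]$ °C in steps of 0.01) minimizing the RMSE.

**ADTS (accumulated days transferred to a standardized temperature).** The
rate is Arrhenius, $r = \exp(B - E_a / (R T_K))$ with $T_K$ in Kelvin,
$R = 1.987 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. A day at temperature
$T$ is worth
$\mathrm{DTS}(T) = \exp\!\big(E_a (T_K - T_s) / (R\, T_K T_s)\big)$
days at the standard temperature $T_s = 298.15$ K (25 °C); this ratio of
rates eliminates the pre-exponential constant, leaving $S$ and $E_a$ to be
estimated by a full grid search (defaults $S \in 1..90$,
$E_a \in [1, 40]$ kcal mol$^{-1}$ step 0.1).

**ADP (accumulated developmental progress).** Any registered rate equation
$r(\mathbf P; T)$ may drive the accumulation; the event is predicted when
accumulated daily progress reaches 100%. Four families are provided:
linear, Arrhenius (with the pre-exponential scaled by $10^{12}$ so the
fitted intercept $B$ is of order one), the Logan equation (left-skewed
bell), and the three-parameter logistic (sigmoid, evaluated in °C, where
$K_0$ is the rate at 0 °C). For each candidate $S$, $\mathbf P$ is
estimated by Nelder--Mead minimization of the RMSE (objective and
parameter tolerance $10^{-8}$, at most 2000 iterations per start); the
$(S, \hat{\mathbf P})$ pair with the global minimum wins.

Numerical choices that matter:

* **Tie-breaks.** All grid searches are deterministic: the smallest $S$,
  then the smallest parameter value, wins ties.
* **Non-attainment.** If a candidate's accumulation never reaches the
  requirement, grid candidates receive an infinite objective, while inside
  the ADP simplex the year's residual becomes
  $(\mathrm{DOY}_{last} - E_i) + 100\,\times$ deficit -- finite and
  decreasing as the deficit shrinks, so the simplex can walk back into the
  feasible region.
* **Initialization.** The Arrhenius ADP start is chained from a coarse
  equivalent-days scan ($E_a$ minimizing the coefficient of variation of
  the annual requirement, $B$ set so mean progress at the observed dates
  is exactly 1); Logan/logistic start from literature-scale values with
  five deterministically jittered restarts. Each candidate $S$ also warm
  starts from the previous candidate's solution.
* **Units.** Temperatures are stored in °C; conversion to Kelvin
  ($T + 273.15$ exactly) happens in exactly one place, inside the
  Arrhenius-type evaluations.
* **Windows.** Accumulation windows include both $S$ and $E_i$. Day-of-year
  is 1-based; 29 February is kept as a native day of its own year, so DOY
  values in leap years are shifted by one after February -- the package
  does not renumber dates across leap years, and windows are always built
  from calendar dates.

## Stage two: fall-winter features and the residual GAM

Residuals $y_i = E_i - \hat E_i$ (positive = later than predicted) are
modelled on six per-year FWT summaries computed over the window from
1 November of the preceding year to the day *before* the starting date
(the chilling-hours accumulation is defined with that exclusive endpoint;
for internal consistency all six features share the window, and an
inclusive-endpoint variant is available as `include_start = TRUE`):

| feature | meaning |
|---|---|
| `x1` | days with $T_{min} \le$ a critical low temperature |
| `x2` | accumulated chilling hours |
| `x3` | mean of daily minima |
| `x4` | mean of daily maxima |
| `x5` | mean of daily means |
| `x6` | minimum of daily minima |

Chilling hours follow the classical Chilling Hours model: each day's 24
hourly temperatures are interpolated from the daily minimum and maximum by
a sine curve,
$T_w = \frac{T_{max}-T_{min}}{2}\sin(\frac{\pi}{12}w - \frac{\pi}{2}) +
\frac{T_{max}+T_{min}}{2}$, $w = 1..24$ (maximum at hour 12, minimum at
hour 24, no solar-time correction), and hours strictly between the bounds
(defaults 0 and 7.2 °C; boundary hours count zero) are chilling hours.

The critical low temperature defining `x1` is not assumed: a scan over
candidates (default $-10..7$ °C step 0.1) refits the chosen GAM formula at
each candidate and keeps the one maximizing deviance explained. A
nearly-flat profile (spread below 5 percentage points) triggers a warning,
since the scan then carries little information.

GAMs are Gaussian with one penalized thin-plate smooth per feature, basis
dimension 6 per term, and GCV smoothing selection (via `mgcv`). The small
basis is deliberate: with a few dozen years, generous bases overfit, and
an overfitted chilling smooth shows up as an implausibly undulant partial
effect. Candidate models (a ten-formula set spanning the full six-feature
model, its drop-one reductions, and three smaller models) are compared by
the rule: among candidates whose every smooth is significant at the 0.05
level (Wald-type approximate tests), the highest deviance explained wins;
if none qualifies, the lowest-AIC candidate is returned with a warning.
AIC values are `mgcv`'s penalized-likelihood AIC; because AIC is
implementation-specific, the tested contract is the ordering of models,
not the values.

The selected model's deviance explained $DE_0$ is partitioned into
per-feature contribution rates by inverse drop-one deviances:
$CR_i = \frac{1/DE_i}{\sum_j 1/DE_j} DE_0 \times 100\%$, where $DE_j$ is
the deviance explained after dropping feature $j$. The rates sum to
$DE_0 \times 100$ by construction; a drop-one model explaining zero
deviance is an error, with the advice to drop that feature. Finally,
adjusted predictions $\hat E_i + \hat y_i$ are formed and the adjusted
RMSE reported; because the GAM contains an intercept, the in-sample
adjusted RMSE can never exceed the unadjusted one.

## The synthetic-data generator

`simulate_climate()` produces daily series with a seasonal sinusoid
(defaults: annual mean 12 °C, half-amplitude 15 °C, coldest day-of-year
15), AR(1) daily anomalies ($\phi = 0.7$, innovation SD 2 °C) and a
jittered diurnal spread (mean range 8 °C, half-range jitter SD 1.5 °C,
clamped so $T_{min} \le T_{mean} \le T_{max}$ always holds). These
defaults emulate a mid-latitude continental climate -- sub-zero January
means and roughly 100--130 chill-capable days per fall-winter window --
matching the kind of station record this analysis is designed for.

`simulate_ffd()` forward-simulates the event date: accumulated progress of
a known rate model (default Arrhenius $B = -4.38$,
$E_a = 15.04$ kcal mol$^{-1}$, $S = 47$, which yields flowering around
day-of-year 95--105 under the default climate) reaches 100%; optional
centered linear FWT effects and Gaussian observation noise are added; the
observed day is rounded to a whole day because real phenological records
are whole days, while the ground-truth log keeps every fractional
component. The validation scenario used by the package's own acceptance
checks activates chilling-hour and daily-maxima effects
(`x2` slope $-0.015$ d per chilling hour, `x4` slope $-6$ d per °C,
1-day observation noise), chosen once to give an unadjusted RMSE of about
4--5.5 days falling to roughly 0.4--1.7 days after adjustment -- the same
qualitative two-stage structure the method is meant to capture in real
series.

What the generator does *not* emulate: weather fronts and multi-day
synoptic structure beyond AR(1), skewed or heavy-tailed anomaly
distributions, trends or regime shifts across years, missing days, and
photoperiod-limited species. Passing the recovery checks therefore shows
the estimators are consistent under the model's own assumptions, not that
those assumptions hold for any particular station.

## Known limitations

* **Starting-date resolution under whole-day records.** With observations
  rounded to whole days, the RMSE floor is $\sqrt{1/12} \approx 0.29$ d,
  while the objective separation between the true $S$ and its neighbours
  is an order of magnitude smaller under realistic winter temperature
  variability. The grid argmin for $S$ is therefore reliable only to
  about $\pm 1$ day (the activation energy remains identifiable to a few
  percent). With unrounded observations the true $S$ is recovered exactly
  with zero RMSE. Users comparing nearby starting dates should inspect
  the full objective profile (`fit$search`) rather than trust the argmin
  to the day.
* **Collinear window means.** `x3`, `x4` and `x5` are correlated above
  0.9 in both synthetic and typical real climates, so attribution among
  them (and the significance pattern of the candidate table) is fragile;
  the contribution-rate partition is conditional on the selected formula.
* **In-sample adjustment.** The reported adjusted RMSE is in-sample; no
  cross-validation machinery is provided, matching the analysis this
  package implements.
* **Chill metrics.** Only the Chilling Hours model is implemented (with
  configurable bounds, e.g. an upper threshold of 4 °C instead of 7.2 °C);
  Utah or Dynamic chill-portions models are out of scope.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script run entirely on generated
data at desk scale, chosen as the smallest sizes that exercise each
property: 1,000 random accumulation instances against a 24-substep
refinement oracle; 10,000 random days against exhaustive hourly
enumeration; a 7,500-point temperature grid for the DTS/rate-ratio
identity; 40-year studies with candidate starts 42..52 and 10 seeded
replicates for the end-to-end recovery experiments; and a 13-year study
for the remaining unit checks.
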