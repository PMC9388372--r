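---
title: "Two-stage distributed-lag analysis of temperature and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage distributed-lag analysis of temperature and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

## The design

Short-term associations between daily ambient temperature and mortality are
non-linear (risk rises on both sides of an optimum) and lagged (cold effects
in particular stretch over weeks). The two-stage design implemented here
handles both while pooling information across many heterogeneous cities.

### Stage 1: city-specific conditional Poisson distributed-lag models

For one city, daily death counts $d_t$ are Poisson with

$$\log \mu_t = \alpha_{s(t)} + \boldsymbol{w}_t'\boldsymbol{\theta} + \log N_{y(t)},$$

where $s(t)$ indexes the **stratum** of day $t$ — the full year × month ×
day-of-week cross-classification, so each stratum holds the 4–5 same
weekdays of one calendar month — and $N_{y(t)}$ is the annual population
offset. Conditioning on stratum totals eliminates the $\alpha$'s exactly
(the conditional likelihood is a product of multinomials), which is what
`fit_conditional_poisson()` maximises; the contract, enforced in the tests,
is numerical identity with the explicit fixed-effects Poisson fit. Because
the strata absorb everything that varies at monthly or slower timescales,
inference rests on *short-term* temperature variability only — an assumption
revisited under "What the generator shows" below.

$\boldsymbol{w}_t$ is a row of the **cross-basis**: the tensor product of

* an exposure basis — a natural cubic spline in daily mean temperature with
  internal knots at the city's 10th, 75th and 90th percentiles and boundary
  knots at its observed min and max (4 columns, linear beyond the
  boundaries), and
* a lag basis over lags 0–21 days — a natural cubic spline with intercept
  and 3 internal knots equally spaced on the $\log(\text{lag}+1)$ scale
  (5 columns), the convention of the two-stage multi-city literature for
  letting effects decay smoothly over three weeks.

Row $t$ therefore depends on the exposures of days $t, t-1, \dots, t-21$
only. Summing the fitted surface over integer lags 0–21 (`reduce_to_overall()`)
yields **4 reduced spline coefficients** describing the cumulative
exposure–response curve; all later work happens on this 4-dimensional scale.

### Stage 2: multivariate random-effects meta-regression

City curves $\boldsymbol{y}_i$ (the reduced coefficients, with within-city
covariance $S_i$) are pooled as

$$\boldsymbol{y}_i \sim N(\Theta'\boldsymbol{x}_i,\; S_i + \Psi),$$

with meta-predictors $\boldsymbol{x}_i$ = (intercept, median observed daily
temperature, temperature range, country) and an unstructured $4\times4$
between-city covariance $\Psi$ estimated by REML. `blup()` then smooths each
city: the BLUP is the meta-prediction plus
$\Psi(\Psi+S_i)^{-1}(\boldsymbol{y}_i - \text{prediction})$, so imprecise
small-city curves borrow strength while data-rich cities keep their own
shape. Because first-stage bases sit on *city-specific* percentiles, the
pooled coefficients describe an "average city" on the percentile scale;
`pooled_curve()` therefore predicts on the element-wise average of the city
knot positions (`average_exposure_spec()`), not on any single city's basis.

### Risk summaries

From a smoothed curve and the city's observed temperatures:

* **MMT** — the observed temperature minimising predicted log-RR
  (`find_mmt()`; ties broken toward the median). The curve is recentred at
  the MMT exactly, by basis-difference algebra.
* **Tail RRs** — $\exp(\text{logRR})$ at the 5th/95th percentiles vs the
  MMT, delta-method CIs.
* **Extreme slopes** — $[\text{logRR}(T_{99}) - \text{logRR}(T_{95})] /
  (T_{99}-T_{95})$ (heat; cold analogously with the 1st and 5th
  percentiles, per 1 °C *decrease*), exponentiated to RR per 1 °C.
* **Excess death fractions** — per day $\mathrm{AF}_t = 1 -
  e^{-\text{logRR}(x_t)}$; attributable deaths $\sum \mathrm{AF}_t n_t$ over
  a component's days (heat: above MMT; cold: below; extreme: beyond the
  95th/5th percentiles; total: off-MMT), as a percentage of all deaths.
  Heat and cold EDFs partition the total exactly. Study-level EDFs are
  death-weighted (summed attributable over summed deaths), never averages
  of city percentages.

Uncertainty for EDFs and slopes is Monte Carlo: coefficient draws from
$N(\hat{\boldsymbol\beta}, \hat V)$, the summary recomputed per draw, and
empirical 2.5/97.5 percentiles reported. One shared draw set per city keeps
the heat/cold/total additivity exact within every draw. Two deliberate
simplifications, recorded here and in the output metadata: the MMT is held
at its point estimate across draws (its sampling uncertainty is not
propagated), and attribution applies the lag-cumulated curve to each day's
temperature (the standard "backward" simplification) rather than resolving
individual lag contributions.

### Cause-specific outcomes: clustering and grouped models

Daily counts for specific causes are too sparse for city-level fits, so
cities are grouped by Ward's minimum-variance hierarchical clustering
(`ward_cluster()`, squared-Euclidean criterion via the classical
Lance–Williams recurrence) on their empirical temperature CDFs evaluated on
a common 0.5 °C grid — the full distribution, not just mean and variance.
`fit_group_model()` then fits one conditional Poisson model per cluster with
strata city × year × month × day-of-week and exposure knots from the pooled
within-cluster temperatures. Rows are pre-sorted by city id so results are
input-order invariant.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| exposure knots | P10/P75/P90 + min/max | °C | standard in the multi-city literature; gives 4 reduced coefficients |
| max lag | 21 | days | captures the long cold tail |
| lag knots | 3, log-spaced | — | finer resolution at short lags where effects change fastest |
| extreme tails | 5th/95th pct | — | ≈ 18 days per year each |
| slope percentiles | 1/5/95/99 | — | tail steepness per 1 °C |
| Monte Carlo draws | 1000 | — | CI stability; seed required |
| cluster count k | 12 (3 used on synthetic data) | — | configurable |
| temperature range predictor | max − min | °C | IQR available as alternative |

## What the synthetic generator emulates — and what it does not

`city_scenario()` / `simulate_study()` generate: seasonal AR(1) daily
temperatures (sinusoidal annual cycle, configurable amplitude, persistence
and innovation sd); Poisson counts driven by a known asymmetric V-shaped
cumulative curve with its minimum at `mmt_true`, distributed over lags
(heat concentrated on lags 0–3 with geometric decay, cold spread over
0–21); multiplicative day-of-week effects; a seasonal confounder in the
death rate; and age/cause strata by fixed-proportion thinning. The calendar
is real dates with Feb 29 dropped (365-day years keep strata sizes
regular); the 21 pre-series exposure days are back-filled with the first
observed value, and fitting excludes the first 21 days as burn-in.

Default magnitudes were chosen once, on realism grounds: baseline 15
deaths/day (a mid-size city), cumulative heat slope RR 1.05 and cold slope
RR 1.034 per °C (magnitudes typical of published multi-city estimates),
day-of-week factors up to 1.03, seasonal confounding amplitude 0.05 on the
log scale. The confounder **lags the temperature cycle by 30 days** —
winter respiratory epidemics trail the temperature minimum — rather than
being phase-locked to it: a confounder exactly in phase with temperature is
collinear with the lagged cold exposure at sub-month resolution, which no
calendar-stratified design can separate, so phase-locking would test a
property the design never claims. Even so, the lagged confounder leaves a
quantifiable residual: in oracle refits with the true functional form, the
slow (21-day) cold slope is attenuated roughly 18% and the fast heat slope
about 5%. Passing recovery tests on these data therefore demonstrate that
the implementation extracts what the design identifies — not that the
design is immune to seasonal confounding.

The generator does not emulate: spatial correlation between cities,
epidemic (influenza) co-circulation, heat waves beyond what AR(1)
persistence produces, population trends, reporting artefacts, or
missingness. Real-data analyses face all of these.

## Numerical choices

* Conditional Poisson: Fisher scoring with step-halving, relative
  log-likelihood tolerance $10^{-9}$, max 100 iterations; per-stratum
  max-subtraction before exponentiation; zero-death strata dropped (no
  conditional information) with the count reported; Pearson dispersion
  computed, and optional quasi-Poisson vcov scaling by
  $\max(1, \text{dispersion})$ — off by default.
* REML: $\Psi$ parameterised by its Cholesky factor (log diagonal), fixed
  effects profiled out by GLS at every $\Psi$; BFGS from a moment start,
  with a Nelder–Mead polish if BFGS reports non-convergence. The
  independent cross-check in the tests is `metafor::rma.mv`.
* Percentiles: linear-interpolation empirical quantiles everywhere (knots,
  tails, Monte Carlo CIs).
* MMT search: over the observed temperatures exactly, ties toward the
  median; degenerate tail gaps ($T_{99}=T_{95}$) are rejected rather than
  returning infinite slopes.
* Curves are first centred at the city median temperature and recentred at
  the MMT after estimation — exact, since only basis differences enter any
  reported contrast.

## Known limitations

* A natural cubic spline cannot reproduce the kink of a piecewise-linear
  V: with knots at P10/P75/P90 and a heat/cold slope asymmetry, the
  smoothed minimum sits slightly to the flat (cold) side of the true MMT
  even in the large-data limit (about −0.6 °C under the default scenario).
  At realistic city sizes, occasional cities whose estimated cold arm dips
  below zero at the far cold tail put the MMT at the coldest observed day;
  BLUP smoothing reduces but does not eliminate this, and restricting the
  search window does not help when the whole estimated cold arm is
  decreasing. City-level MMTs from a few years of data should be read with
  this in mind.
* Residual sub-month seasonal confounding attenuates slow lagged effects
  (see above); the design's strata cannot remove it, only moderate it.
* Type-I error and CI calibration are verified on a *true* null
  (temperature-independent mortality, no seasonal confounder); with a
  seasonal confounder present the outcome is genuinely associated with
  temperature, and rejections there are not errors.
* Problem sizes used in the shipped validation: 20 cities × 3 years for
  recovery runs (25 replicates), 100 three-year cities for null
  calibration, 40 curves × 50 replicates for heterogeneity recovery —
  chosen to exercise every code path at desk scale while keeping the suite
  fast.

## Open design decisions

Where the design left a choice, the package picks one and records it in
output metadata: the temperature-range meta-predictor is max − min
(IQR selectable); the pooled curve is reported at the estimation-sample
mean design row (any predictor point can be supplied); strata use the full
dow × month × year triple interaction; overdispersion scaling is off by
default; EDF/slope intervals are Monte Carlo rather than delta-method.
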