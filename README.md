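# tempmort

Two-stage distributed-lag analysis of daily ambient temperature and
mortality, of the kind used in large multi-city environmental epidemiology
studies. The package is aimed at analysts who have per-city daily time
series (date, mean temperature, death counts, annual population) and want
city-specific and pooled exposure–response curves together with the standard
risk summaries — plus a synthetic-data generator with known ground truth for
validating the whole chain, since real vital-registration data are rarely
shareable.

## The model

**Stage 1 (within city).** Daily death counts are modelled by a conditional
Poisson regression: counts in day *t* follow Poisson(μ_t) with

    log μ_t = α_{s(t)} + w_t' θ + log(population in year of t)

where `s(t)` is the day's stratum — the full year × month × day-of-week
cross-classification, which absorbs seasonality and secular trends — and
`w_t` is a **cross-basis** row: the tensor product of a natural cubic spline
in temperature (knots at the city's 10th/75th/90th percentiles, boundaries
at its min/max → 4 columns) and a natural cubic spline in lag over 0–21
days (intercept + 3 knots log-spaced in lag → 5 columns). The stratum
intercepts α are never estimated: conditioning on stratum death totals gives
a multinomial likelihood in θ alone, numerically identical to the
fixed-effects fit. Summing the fitted surface across lags 0–21 reduces θ
(20 numbers) to **4 reduced spline coefficients** describing the cumulative
temperature–mortality curve.

**Stage 2 (between cities).** The per-city reduced coefficients `y_i` are
pooled by multivariate random-effects meta-regression,
`y_i ~ N(Θ'x_i, S_i + Ψ)`, with meta-predictors `x_i` = (median temperature,
temperature range, country), within-city covariance `S_i` from stage 1 and
an unstructured between-city covariance Ψ estimated by REML. Each city's
curve is then smoothed by BLUP — shrunk toward its meta-regression
prediction in proportion to its imprecision.

**Risk summaries.** From each smoothed curve: the minimum mortality
temperature (MMT; the observed temperature minimising the curve), relative
risks at the 5th/95th temperature percentiles versus the MMT,
extreme-temperature slopes (log-RR difference between the 99th and 95th — or
1st and 5th — percentiles per °C, as RR per 1 °C), and excess death
fractions — `EDF = 100 · Σ_t (1 − exp(−logRR(x_t))) n_t / Σ_t n_t` —
partitioned into heat/cold and extreme (≥P95 / ≤P5) components, with Monte
Carlo confidence intervals from coefficient draws. Cities can also be
grouped by Ward clustering of their empirical temperature CDFs, with grouped
conditional Poisson fits (strata additionally crossed with city) for sparse
cause-specific outcomes.

## Worked example

```r
library(tempmort)

study <- simulate_study(20, city_scenario(n_years = 3),
                        heterogeneity = 0.005, master_seed = 4,
                        mmt_percentile = 75)
cfg <- run_config(n_cities = 20, n_years = 3, master_seed = 4, n_draws = 500L)
res <- run_pipeline(cfg, cities = study$cities, quiet = TRUE)

res$pooled_edf
#>   total_deaths edf_total edf_heat edf_cold edf_extreme_heat edf_extreme_cold
#> 1       395860  10.26901 1.837807 8.431199        0.9699799         1.456015

round(cor(res$summaries$mmt, study$truth$mmt_true), 2)
#> [1] 0.98
```

The pooled EDF row says that in this simulated study 10.3% of all deaths are
attributable to non-optimal temperatures — 1.8% to heat (days above each
city's MMT) and 8.4% to cold, with the extreme tails (beyond the city 95th/
5th percentiles) contributing 1.0% and 1.5% — and the per-city MMT estimates
track the known true MMTs. Per-city summaries (MMT, tail RRs, slopes, EDF
components with CIs) are in `res$summaries`, one row per city.

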