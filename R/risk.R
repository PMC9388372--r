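# Headline risk summaries from smoothed curves: minimum mortality
# temperature, relative risks at tail percentiles, extreme-temperature
# slopes, and excess death fractions with Monte Carlo confidence intervals.

#' Find the minimum mortality temperature (MMT)
#'
#' The observed daily temperature at which the lag-cumulated curve attains
#' its minimum predicted log-RR. Evaluation is restricted to the observed
#' temperatures themselves (not a continuous grid); ties are broken toward
#' the median observed temperature.
#'
#' @param curve A [reduced_curve()] (typically a BLUP-smoothed city curve).
#' @param observed_temps The city's observed daily temperatures (degrees C).
#' @return The MMT in degrees C.
#' @export
find_mmt <- function(curve, observed_temps) {
  stopifnot(inherits(curve, "reduced_curve"))
  if (!length(observed_temps)) stop_tm("no observed temperatures")
  u <- sort(unique(as.numeric(observed_temps)))
  logrr <- predict_curve(curve, u)$logrr
  lo <- min(logrr)
  cand <- u[logrr <= lo + 1e-12]
  if (length(cand) == 1L) return(cand)
  med <- empirical_percentile(observed_temps, 50)
  cand[which.min(abs(cand - med))]
}

# Day-index sets for the attribution components. Extreme thresholds are the
# city's 5th/95th temperature percentiles.
component_days <- function(temps, mmt, component,
                           extreme_percentiles = c(5, 95)) {
  p <- empirical_percentile(temps, extreme_percentiles)
  switch(component,
         "heat"         = which(temps > mmt),
         "cold"         = which(temps < mmt),
         "extreme_heat" = which(temps >= p[2]),
         "extreme_cold" = which(temps <= p[1]),
         "total"        = which(temps != mmt),
         stop_tm("unknown component `%s`", component))
}

#' Attributable deaths and excess death fraction for one component
#'
#' Backward attributable fraction from the lag-cumulated curve: for each day
#' `t`, `AF_t = 1 - exp(-logRR(x_t))`; attributable deaths are
#' `sum_{t in component} AF_t n_t` and the excess death fraction (EDF) is
#' that sum as a percentage of all deaths. Components: `heat` (days above
#' the MMT), `cold` (below), `extreme_heat` (at or above the 95th
#' percentile), `extreme_cold` (at or below the 5th), `total` (all days off
#' the MMT). The curve must be centred at the MMT.
#'
#' @param curve A [reduced_curve()] recentred at the MMT (checked:
#'   `|logRR(mmt)|` must be `<= 1e-9`).
#' @param series A [daily_city_series()].
#' @param mmt The minimum mortality temperature used as reference.
#' @param component One of `"heat"`, `"cold"`, `"extreme_heat"`,
#'   `"extreme_cold"`, `"total"`.
#' @param outcome Death-count column (default `"all"`).
#' @param extreme_percentiles Tail percentiles defining the extreme
#'   components (default `c(5, 95)`).
#' @return List with `attributable_deaths`, `edf_pct` and `total_deaths`.
#' @export
attributable_fraction <- function(curve, series, mmt, component = "total",
                                  outcome = "all",
                                  extreme_percentiles = c(5, 95)) {
  stopifnot(inherits(curve, "reduced_curve"),
            inherits(series, "daily_city_series"))
  if (abs(predict_curve(curve, mmt)$logrr) > 1e-9)
    stop_tm("curve is not recentred at the MMT (logRR(%.3f) != 0); use recentre_curve()", mmt)
  temps <- series$data$temp_c
  col <- if (grepl("^deaths_", outcome)) outcome else paste0("deaths_", outcome)
  n_t <- series$data[[col]]
  idx <- component_days(temps, mmt, component, extreme_percentiles)
  total <- sum(n_t)
  if (!length(idx))
    return(list(attributable_deaths = 0, edf_pct = 0, total_deaths = total))
  af <- 1 - exp(-predict_curve(curve, temps[idx])$logrr)
  ad <- sum(af * n_t[idx])
  list(attributable_deaths = ad, edf_pct = 100 * ad / total,
       total_deaths = total)
}

# EDFs for several components from one coefficient matrix (k x n_draws or a
# single k-vector): shared machinery for point estimates and Monte Carlo
# draws, guaranteeing additivity within a draw.
edf_from_coefs <- function(curve, series, mmt, components, coefs,
                           outcome = "all", extreme_percentiles = c(5, 95)) {
  temps <- series$data$temp_c
  col <- if (grepl("^deaths_", outcome)) outcome else paste0("deaths_", outcome)
  n_t <- series$data[[col]]
  total <- sum(n_t)
  X <- centred_basis(recentre_curve(curve, mmt), temps)   # days x k
  logrr <- X %*% coefs                                    # days x n_draws
  af_n <- (1 - exp(-logrr)) * n_t
  out <- matrix(0, length(components), ncol(coefs),
                dimnames = list(components, NULL))
  for (cm in components) {
    idx <- component_days(temps, mmt, cm, extreme_percentiles)
    if (length(idx))
      out[cm, ] <- 100 * colSums(af_n[idx, , drop = FALSE]) / total
  }
  out
}

#' Monte Carlo confidence interval for an excess death fraction
#'
#' Draws coefficient vectors from a multivariate normal with the curve's
#' coefficients and covariance, recomputes the EDF per draw (the MMT is held
#' fixed at its point estimate), and reports the empirical 2.5th and 97.5th
#' percentiles.
#'
#' @inheritParams attributable_fraction
#' @param n_draws Number of Monte Carlo draws (>= 100; default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @return List with `estimate`, `ci_low`, `ci_high` (percent), and the
#'   `draws`.
#' @export
edf_confidence <- function(curve, series, mmt, component = "total",
                           outcome = "all", n_draws = 1000L, seed,
                           extreme_percentiles = c(5, 95)) {
  if (n_draws < 100L) stop_tm("n_draws must be >= 100")
  if (missing(seed)) stop_tm("`seed` is required")
  est <- attributable_fraction(recentre_curve(curve, mmt), series, mmt,
                               component, outcome, extreme_percentiles)
  if (any(!is.finite(curve$vcov)) || any(diag(curve$vcov) < 0))
    stop_tm("degenerate curve covariance")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- t(rmvnorm_chol(n_draws, curve$coef, curve$vcov))  # k x n_draws
  edfs <- edf_from_coefs(curve, series, mmt, component, draws,
                         outcome, extreme_percentiles)[component, ]
  ci <- empirical_percentile(edfs, c(2.5, 97.5))
  list(estimate = est$edf_pct, ci_low = ci[1], ci_high = ci[2], draws = edfs)
}

#' Extreme-temperature slope: RR per 1 degree C in the tail
#'
#' Heat: `exp[(logRR(T99) - logRR(T95)) / (T99 - T95)]`, the RR per 1 C
#' higher temperature above the 95th percentile. Cold:
#' `exp[(logRR(T1) - logRR(T5)) / (T5 - T1)]`, the RR per 1 C *lower*
#' temperature below the 5th percentile. Confidence intervals come from the
#' same Monte Carlo coefficient draws used for the EDFs.
#'
#' @param curve A [reduced_curve()].
#' @param observed_temps The city's observed daily temperatures.
#' @param side `"heat"` or `"cold"`.
#' @param n_draws,seed Monte Carlo draws for the CI; `seed` required.
#' @return List with `rr_per_c`, `ci_low`, `ci_high`.
#' @export
extreme_slope <- function(curve, observed_temps, side = c("heat", "cold"),
                          n_draws = 1000L, seed) {
  side <- match.arg(side)
  stopifnot(inherits(curve, "reduced_curve"))
  if (missing(seed)) stop_tm("`seed` is required")
  pr <- if (side == "heat") c(95, 99) else c(5, 1)
  tt <- empirical_percentile(observed_temps, pr)
  gap <- if (side == "heat") tt[2] - tt[1] else tt[1] - tt[2]  # T99-T95 / T5-T1
  if (gap <= 0)
    stop_tm("degenerate temperature distribution: zero gap between the %s tail percentiles", side)
  B <- centred_basis(curve, tt)                 # rows: (T95, T99) or (T5, T1)
  contrast <- drop(B[2, ] - B[1, ]) / gap
  est <- exp(sum(contrast * curve$coef))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- rmvnorm_chol(n_draws, curve$coef, curve$vcov)
  slopes <- exp(drop(draws %*% contrast))
  ci <- empirical_percentile(slopes, c(2.5, 97.5))
  list(rr_per_c = est, ci_low = ci[1], ci_high = ci[2])
}

#' Relative risk at a temperature percentile, versus the MMT
#'
#' `exp(logRR)` at the empirical percentile `p` of the observed
#' temperatures, with the curve centred at the MMT; delta-method CI.
#'
#' @param curve A [reduced_curve()] recentred at the MMT.
#' @param observed_temps Observed daily temperatures.
#' @param p Percentile (0-100).
#' @return List with `temp`, `rr`, `ci_low`, `ci_high`.
#' @export
rr_at_percentile <- function(curve, observed_temps, p) {
  stopifnot(inherits(curve, "reduced_curve"))
  tt <- empirical_percentile(observed_temps, p)
  pred <- predict_curve(curve, tt)
  list(temp = tt, rr = pred$rr, ci_low = pred$rr_low, ci_high = pred$rr_high)
}

#' Full risk summary for one city
#'
#' Computes the MMT, tail RRs, extreme-temperature slopes and all EDF
#' components with Monte Carlo CIs, using one shared draw set so that
#' `edf_heat + edf_cold = edf_total` holds within every draw.
#'
#' @param curve The city's (smoothed) [reduced_curve()].
#' @param series The city's [daily_city_series()].
#' @param outcome Death-count column (default `"all"`).
#' @param n_draws,seed Monte Carlo control; `seed` required.
#' @param extreme_percentiles Tail percentiles for the extreme components.
#' @param slope_percentiles Percentiles for the RR summaries (default
#'   `c(5, 95)`).
#' @return A one-row `data.frame` of class `"risk_summary"` with the MMT,
#'   `rr_p95`/`rr_p5` (+ CIs), `slope_heat_rr`/`slope_cold_rr` (+ CIs), the
#'   five EDF components (+ CIs) and attributable deaths.
#' @export
risk_summary <- function(curve, series, outcome = "all", n_draws = 1000L,
                         seed, extreme_percentiles = c(5, 95),
                         slope_percentiles = c(5, 95)) {
  stopifnot(inherits(curve, "reduced_curve"),
            inherits(series, "daily_city_series"))
  if (missing(seed)) stop_tm("`seed` is required")
  temps <- series$data$temp_c
  mmt <- find_mmt(curve, temps)
  cmmt <- recentre_curve(curve, mmt)
  comps <- c("total", "heat", "cold", "extreme_heat", "extreme_cold")
  point <- edf_from_coefs(curve, series, mmt, comps,
                          matrix(curve$coef, ncol = 1), outcome,
                          extreme_percentiles)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- t(rmvnorm_chol(n_draws, curve$coef, curve$vcov))
  edfs <- edf_from_coefs(curve, series, mmt, comps, draws, outcome,
                         extreme_percentiles)
  ci <- apply(edfs, 1L, empirical_percentile, p = c(2.5, 97.5))
  rr_hi <- rr_at_percentile(cmmt, temps, slope_percentiles[2])
  rr_lo <- rr_at_percentile(cmmt, temps, slope_percentiles[1])
  sl_h <- extreme_slope(cmmt, temps, "heat", n_draws, seed)
  sl_c <- extreme_slope(cmmt, temps, "cold", n_draws, seed)
  col <- if (grepl("^deaths_", outcome)) outcome else paste0("deaths_", outcome)
  total_deaths <- sum(series$data[[col]])
  out <- data.frame(
    city_id = series$city_id, mmt = mmt,
    rr_p95 = rr_hi$rr, rr_p95_low = rr_hi$ci_low, rr_p95_high = rr_hi$ci_high,
    rr_p5 = rr_lo$rr, rr_p5_low = rr_lo$ci_low, rr_p5_high = rr_lo$ci_high,
    slope_heat_rr = sl_h$rr_per_c, slope_heat_low = sl_h$ci_low,
    slope_heat_high = sl_h$ci_high,
    slope_cold_rr = sl_c$rr_per_c, slope_cold_low = sl_c$ci_low,
    slope_cold_high = sl_c$ci_high,
    total_deaths = total_deaths)
  for (cm in comps) {
    out[[paste0("edf_", cm)]] <- point[cm, 1]
    out[[paste0("edf_", cm, "_low")]] <- ci[1, cm]
    out[[paste0("edf_", cm, "_high")]] <- ci[2, cm]
    out[[paste0("attr_deaths_", cm)]] <- point[cm, 1] * total_deaths / 100
  }
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Pool per-city risk summaries to the study level
#'
#' Study-level EDFs are death-weighted: summed attributable deaths over
#' summed total deaths (not an average of city EDFs).
#'
#' @param summaries A `data.frame` of stacked [risk_summary()] rows.
#' @return One-row `data.frame` of pooled EDFs (percent) and totals.
#' @export
pool_edf <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  tot <- sum(summaries$total_deaths)
  out <- data.frame(total_deaths = tot)
  for (cm in c("total", "heat", "cold", "extreme_heat", "extreme_cold"))
    out[[paste0("edf_", cm)]] <-
      100 * sum(summaries[[paste0("attr_deaths_", cm)]]) / tot
  out
}
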