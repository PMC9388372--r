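# Synthetic multi-city daily temperature and mortality series with a known
# lagged exposure-response surface. Vital-registration data of the kind this
# design is applied to are rarely public, so validation runs on generated
# data where the ground truth is known exactly.

#' Define a true lagged temperature-mortality surface
#'
#' A V-shaped (piecewise log-linear, asymmetric) cumulative exposure-response
#' with its minimum at `mmt_true`, distributed over lags 0..21 by fixed
#' nonnegative weights summing to 1. The cumulative log-RR at temperature `x`
#' is `heat_log_slope * max(0, x - mmt_true) + cold_log_slope * max(0,
#' mmt_true - x)`; the surface value at `(mmt_true, any lag)` is 0.
#'
#' Default lag weights follow the shape reported in the temperature-mortality
#' literature: heat effects concentrated on lags 0-3 (geometric decay), cold
#' effects spread over the full 0-21 window.
#'
#' @param mmt_true True minimum mortality temperature (degrees C).
#' @param heat_log_slope Cumulative log-RR per degree C above `mmt_true`.
#' @param cold_log_slope Cumulative log-RR per degree C below `mmt_true`.
#' @param heat_lag_weights,cold_lag_weights Nonnegative weight vectors over
#'   lags 0..21 summing to 1.
#' @param max_lag Lag window (default 21 days).
#' @return An object of class `"true_surface"`.
#' @export
true_surface <- function(mmt_true, heat_log_slope = log(1.05),
                         cold_log_slope = log(1.034),
                         heat_lag_weights = NULL, cold_lag_weights = NULL,
                         max_lag = 21L) {
  assert_scalar(mmt_true, "mmt_true")
  assert_scalar(heat_log_slope, "heat_log_slope")
  assert_scalar(cold_log_slope, "cold_log_slope")
  max_lag <- as.integer(max_lag)
  if (is.null(heat_lag_weights)) {
    w <- 0.6 ^ (0:max_lag)
    w[(0:max_lag) > 3] <- 0
    heat_lag_weights <- w / sum(w)
  }
  if (is.null(cold_lag_weights)) {
    w <- 0.9 ^ (0:max_lag)
    cold_lag_weights <- w / sum(w)
  }
  for (nm in c("heat_lag_weights", "cold_lag_weights")) {
    w <- get(nm)
    if (length(w) != max_lag + 1L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop_tm("`%s` must be %d nonnegative weights summing to 1", nm, max_lag + 1L)
  }
  structure(list(mmt_true = mmt_true, heat_log_slope = heat_log_slope,
                 cold_log_slope = cold_log_slope,
                 heat_lag_weights = as.numeric(heat_lag_weights),
                 cold_lag_weights = as.numeric(cold_lag_weights),
                 max_lag = max_lag),
            class = "true_surface")
}

#' Cumulative true log-RR curve of a surface
#' @param surface A [true_surface()].
#' @param temps Temperatures (degrees C).
#' @return Numeric vector of cumulative (lag-summed) log-RR values; 0 at
#'   `mmt_true` exactly.
#' @export
true_cumulative_logrr <- function(surface, temps) {
  stopifnot(inherits(surface, "true_surface"))
  surface$heat_log_slope * pmax(0, temps - surface$mmt_true) +
    surface$cold_log_slope * pmax(0, surface$mmt_true - temps)
}

#' Define a synthetic city scenario
#'
#' Bundles everything needed to simulate one city: a seasonal AR(1)
#' temperature process, a Poisson mortality process driven by a
#' [true_surface()], day-of-week effects and seasonal confounding, and the
#' city's annual population.
#'
#' @param city_id Character identifier.
#' @param country Country label (used as a meta-regression predictor).
#' @param n_years Number of 365-day years to simulate (leap days dropped).
#' @param mean_temp Annual mean temperature (degrees C).
#' @param seasonal_amplitude Amplitude of the annual temperature cycle
#'   (degrees C, >= 0).
#' @param ar1_coef AR(1) coefficient of the daily temperature noise, in
#'   `[0, 1)`.
#' @param daily_sd Innovation standard deviation of the noise (degrees C).
#' @param annual_population City population (constant across years).
#' @param baseline_rate Expected deaths per day at the minimum mortality
#'   temperature, mid-season, on the reference weekday.
#' @param true_curve A [true_surface()]; defaults to an asymmetric V with
#'   MMT at `mean_temp + 0.45 * seasonal_amplitude`.
#' @param dow_effects Seven multiplicative weekday factors (Mon..Sun),
#'   all > 0.
#' @param season_confounding_amplitude Amplitude of a seasonal term in the
#'   log death rate that is not mediated by temperature (confounding the
#'   temperature-mortality association through shared seasonality).
#' @param start_year First calendar year of the series.
#' @param seed Integer RNG seed; fixed seed reproduces the city exactly.
#' @return An object of class `"city_scenario"`.
#' @export
city_scenario <- function(city_id = "city01", country = "A", n_years = 3L,
                          mean_temp = 20, seasonal_amplitude = 6,
                          ar1_coef = 0.6, daily_sd = 2,
                          annual_population = 500000L, baseline_rate = 15,
                          true_curve = NULL,
                          dow_effects = c(1, 1, 1, 1, 1, 1.02, 1.03),
                          season_confounding_amplitude = 0.05,
                          start_year = 2002L, seed = 1L) {
  for (nm in c("mean_temp", "seasonal_amplitude", "ar1_coef", "daily_sd",
               "baseline_rate", "season_confounding_amplitude"))
    assert_scalar(get(nm), nm)
  n_years <- as.integer(n_years)
  if (n_years < 1L) stop_tm("n_years must be >= 1")
  if (seasonal_amplitude < 0) stop_tm("seasonal_amplitude must be >= 0")
  if (ar1_coef < 0 || ar1_coef >= 1) stop_tm("ar1_coef must be in [0, 1)")
  if (daily_sd <= 0) stop_tm("daily_sd must be > 0")
  if (annual_population <= 0) stop_tm("annual_population must be > 0")
  if (baseline_rate <= 0) stop_tm("baseline_rate must be > 0")
  if (season_confounding_amplitude < 0) stop_tm("season_confounding_amplitude must be >= 0")
  if (length(dow_effects) != 7L || any(dow_effects <= 0))
    stop_tm("dow_effects must be 7 positive factors")
  if (is.null(true_curve))
    true_curve <- true_surface(mmt_true = mean_temp + 0.45 * seasonal_amplitude)
  stopifnot(inherits(true_curve, "true_surface"))
  structure(list(city_id = as.character(city_id), country = as.character(country),
                 n_years = n_years, mean_temp = mean_temp,
                 seasonal_amplitude = seasonal_amplitude, ar1_coef = ar1_coef,
                 daily_sd = daily_sd,
                 annual_population = as.integer(annual_population),
                 baseline_rate = baseline_rate, true_curve = true_curve,
                 dow_effects = as.numeric(dow_effects),
                 season_confounding_amplitude = season_confounding_amplitude,
                 start_year = as.integer(start_year), seed = as.integer(seed)),
            class = "city_scenario")
}

# 365-day calendar: real dates with Feb 29 dropped, keeping strata regular.
scenario_dates <- function(scenario) {
  d <- seq(as.Date(sprintf("%d-01-01", scenario$start_year)),
           as.Date(sprintf("%d-12-31", scenario$start_year + scenario$n_years - 1L)),
           by = "day")
  d[format(d, "%m-%d") != "02-29"]
}

# Day-of-year 1..365 on the leap-free calendar.
doy365 <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  stats::ave(seq_along(dates), yr, FUN = seq_along)
}

# Annual temperature cycle: peak at mid-year (day ~183).
season_term <- function(doy) sin(2 * pi * doy / 365 - pi / 2)

# Seasonal mortality confounder: same period but lagging the temperature
# cycle by ~30 days, as winter respiratory epidemics lag the temperature
# minimum. (A confounder exactly phase-locked to temperature would be
# collinear with the exposure at sub-month resolution, which no
# calendar-stratified design can separate.)
confound_term <- function(doy) sin(2 * pi * (doy - 30) / 365 - pi / 2)

#' Simulate a city's daily mean temperature series
#'
#' `temp_t = mean_temp + seasonal_amplitude * sin(2 pi doy/365 + phase) +
#' e_t`, where `e_t` is a stationary AR(1) process with coefficient
#' `ar1_coef` and innovation sd `daily_sd`. The phase puts the seasonal peak
#' at mid-year. Length `365 * n_years`.
#'
#' @param scenario A [city_scenario()].
#' @return Numeric vector of daily temperatures (degrees C).
#' @export
simulate_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "city_scenario"))
  dates <- scenario_dates(scenario)
  n <- length(dates)
  seasonal <- scenario$mean_temp +
    scenario$seasonal_amplitude * season_term(doy365(dates))
  withr_seed <- scenario$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  e <- numeric(n)
  marg_sd <- scenario$daily_sd / sqrt(1 - scenario$ar1_coef^2)
  e[1] <- stats::rnorm(1, 0, marg_sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, scenario$daily_sd)
    for (t in 2:n) e[t] <- scenario$ar1_coef * e[t - 1] + innov[t - 1]
  }
  seasonal + e
}

# Preserve/restore the caller's RNG state so generators with their own seeds
# do not perturb the surrounding stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate daily death counts given a temperature series
#'
#' Counts are Poisson with `log mu_t = log(baseline_rate) + log(dow factor) +
#' season_confounding_amplitude * s(doy) + sum_{l=0..21} [heat_log_slope *
#' w_heat_l * max(0, x_{t-l} - mmt) + cold_log_slope * w_cold_l * max(0, mmt
#' - x_{t-l})]`. The 21 pre-series exposure days are back-filled with the
#' first observed temperature; model fitting drops the burn-in days.
#'
#' Stratified counts (ages <65/65+, causes) are produced by thinning the
#' total with fixed proportions, supplying inputs for the grouped
#' cause-specific stage.
#'
#' @param temps Daily temperature series, length `365 * n_years`.
#' @param scenario A [city_scenario()]. Uses `scenario$seed + 1` so counts
#'   are reproducible independently of the temperature draw.
#' @return `data.frame` with `date`, `temp_c` and integer death columns
#'   `deaths_all`, `deaths_65plus`, `deaths_under65`, `deaths_cvd`,
#'   `deaths_resp`, `deaths_respinf`, `deaths_other`.
#' @export
simulate_deaths <- function(temps, scenario) {
  stopifnot(inherits(scenario, "city_scenario"))
  dates <- scenario_dates(scenario)
  if (length(temps) != length(dates))
    stop_tm("temps length %d != 365 * n_years = %d", length(temps), length(dates))
  assert_finite(temps, "temps")
  tc <- scenario$true_curve
  L <- tc$max_lag
  padded <- c(rep(temps[1], L), temps)
  heat_exc <- pmax(0, padded - tc$mmt_true)
  cold_exc <- pmax(0, tc$mmt_true - padded)
  n <- length(temps)
  lag_effect <- numeric(n)
  for (l in 0:L) {
    idx <- (L - l + 1):(L - l + n)
    lag_effect <- lag_effect +
      tc$heat_log_slope * tc$heat_lag_weights[l + 1L] * heat_exc[idx] +
      tc$cold_log_slope * tc$cold_lag_weights[l + 1L] * cold_exc[idx]
  }
  dow <- as.POSIXlt(dates)$wday          # 0 = Sunday
  dow_idx <- ifelse(dow == 0L, 7L, dow)  # 1 = Monday .. 7 = Sunday
  log_mu <- log(scenario$baseline_rate) + log(scenario$dow_effects[dow_idx]) +
    scenario$season_confounding_amplitude * confound_term(doy365(dates)) +
    lag_effect
  if (any(log_mu > log(.Machine$double.xmax) / 2))
    stop_tm("expected daily deaths overflow (log mu up to %.1f); check slopes", max(log_mu))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scenario$seed + 1L)
  d_all <- stats::rpois(n, exp(log_mu))
  # fixed thinning proportions: age split, then cause split within all ages
  p65 <- 0.65
  p_cause <- c(cvd = 0.30, resp = 0.10, respinf = 0.05, other = 0.55)
  d_65 <- stats::rbinom(n, d_all, p65)
  cause <- matrix(0L, n, 4L, dimnames = list(NULL, names(p_cause)))
  pos <- which(d_all > 0)
  if (length(pos))
    cause[pos, ] <- t(vapply(d_all[pos],
                             function(k) stats::rmultinom(1, k, p_cause)[, 1],
                             integer(4L)))
  data.frame(date = dates, temp_c = as.numeric(temps),
             deaths_all = d_all, deaths_65plus = d_65,
             deaths_under65 = d_all - d_65,
             deaths_cvd = cause[, "cvd"], deaths_resp = cause[, "resp"],
             deaths_respinf = cause[, "respinf"], deaths_other = cause[, "other"])
}

#' Assemble a city's daily series object
#'
#' @param scenario A [city_scenario()].
#' @return An object of class `"daily_city_series"`: `city_id`, `country`,
#'   the daily `data` frame from [simulate_deaths()], and a `population`
#'   frame (`year`, `population`).
#' @export
simulate_city <- function(scenario) {
  temps <- simulate_temperature(scenario)
  data <- simulate_deaths(temps, scenario)
  years <- scenario$start_year + seq_len(scenario$n_years) - 1L
  daily_city_series(scenario$city_id, scenario$country, data,
                    data.frame(year = years,
                               population = rep(scenario$annual_population,
                                                length(years))))
}

#' Construct a daily city series
#'
#' The per-city input unit of the first stage: aligned daily temperature and
#' stratified death counts plus annual population.
#'
#' @param city_id,country Identifiers.
#' @param data `data.frame` with `date` (class `Date`, no duplicates),
#'   `temp_c` (finite) and one or more nonnegative integer `deaths_*`
#'   columns.
#' @param population `data.frame` with `year` and `population` covering every
#'   calendar year in `data`.
#' @return An object of class `"daily_city_series"`.
#' @export
daily_city_series <- function(city_id, country, data, population) {
  stopifnot(is.data.frame(data), is.data.frame(population))
  if (!all(c("date", "temp_c") %in% names(data)))
    stop_tm("`data` needs columns `date` and `temp_c`")
  if (anyDuplicated(data$date)) stop_tm("duplicate dates in city %s", city_id)
  assert_finite(data$temp_c, "temp_c")
  dcols <- grep("^deaths_", names(data), value = TRUE)
  if (!length(dcols)) stop_tm("`data` needs at least one `deaths_*` column")
  for (dc in dcols)
    if (any(data[[dc]] < 0)) stop_tm("negative counts in %s", dc)
  yrs <- unique(as.integer(format(data$date, "%Y")))
  if (!all(yrs %in% population$year))
    stop_tm("`population` must cover every year of `data` for city %s", city_id)
  structure(list(city_id = as.character(city_id), country = as.character(country),
                 data = data[order(data$date), , drop = FALSE],
                 population = population),
            class = "daily_city_series")
}

#' @export
print.daily_city_series <- function(x, ...) {
  cat(sprintf("daily city series %s (%s): %d days, %s to %s, %d total deaths\n",
              x$city_id, x$country, nrow(x$data),
              min(x$data$date), max(x$data$date), sum(x$data$deaths_all)))
  invisible(x)
}

#' Simulate a heterogeneous multi-city study with known ground truth
#'
#' Draws per-city scenarios around a template: city mean temperatures and
#' seasonal amplitudes are jittered, and per-city cumulative log-slopes are
#' drawn as `N(template slope, heterogeneity^2)` (truncated at 0 so heat and
#' cold slopes keep their signs). Each city's MMT sits at the same percentile
#' of its own climate as the template's. All randomness derives from
#' `master_seed`.
#'
#' @param n_cities Number of cities (>= 2).
#' @param template A [city_scenario()] template.
#' @param heterogeneity Between-city sd of the cumulative log-slopes.
#' @param master_seed Integer master seed.
#' @param mean_temp_jitter_sd Between-city sd of mean temperature (degrees
#'   C).
#' @param amplitude_jitter_sd Between-city sd of seasonal amplitude.
#' @param mmt_percentile If non-`NULL`, place each city's true MMT at this
#'   percentile of its own simulated temperature series (overriding the
#'   template's MMT position).
#' @return An object of class `"city_study"`: list with `cities` (list of
#'   [daily_city_series()]), `scenarios`, and `truth` (`data.frame` of
#'   per-city true MMT and slopes).
#' @export
simulate_study <- function(n_cities, template = city_scenario(),
                           heterogeneity = 0, master_seed = 1L,
                           mean_temp_jitter_sd = 2, amplitude_jitter_sd = 1,
                           mmt_percentile = NULL) {
  if (n_cities < 2L) stop_tm("n_cities must be >= 2")
  stopifnot(inherits(template, "city_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 2L, n_cities)
  mean_temps <- stats::rnorm(n_cities, template$mean_temp, mean_temp_jitter_sd)
  amps <- pmax(0.5, stats::rnorm(n_cities, template$seasonal_amplitude,
                                 amplitude_jitter_sd))
  tc <- template$true_curve
  heat_slopes <- pmax(0, stats::rnorm(n_cities, tc$heat_log_slope, heterogeneity))
  cold_slopes <- pmax(0, stats::rnorm(n_cities, tc$cold_log_slope, heterogeneity))
  # keep the MMT at the template's relative position within each climate
  mmt_offset <- tc$mmt_true - template$mean_temp
  rel <- if (template$seasonal_amplitude > 0)
    mmt_offset / template$seasonal_amplitude else 0
  scenarios <- vector("list", n_cities)
  cities <- vector("list", n_cities)
  for (i in seq_len(n_cities)) {
    tci <- true_surface(mmt_true = mean_temps[i] + rel * amps[i],
                        heat_log_slope = heat_slopes[i],
                        cold_log_slope = cold_slopes[i],
                        heat_lag_weights = tc$heat_lag_weights,
                        cold_lag_weights = tc$cold_lag_weights,
                        max_lag = tc$max_lag)
    sc_i <- city_scenario(
      city_id = sprintf("city%03d", i), country = template$country,
      n_years = template$n_years, mean_temp = mean_temps[i],
      seasonal_amplitude = amps[i], ar1_coef = template$ar1_coef,
      daily_sd = template$daily_sd,
      annual_population = template$annual_population,
      baseline_rate = template$baseline_rate, true_curve = tci,
      dow_effects = template$dow_effects,
      season_confounding_amplitude = template$season_confounding_amplitude,
      start_year = template$start_year, seed = seeds[i])
    temps_i <- simulate_temperature(sc_i)
    if (!is.null(mmt_percentile)) {
      sc_i$true_curve <- true_surface(
        mmt_true = empirical_percentile(temps_i, mmt_percentile),
        heat_log_slope = heat_slopes[i], cold_log_slope = cold_slopes[i],
        heat_lag_weights = tc$heat_lag_weights,
        cold_lag_weights = tc$cold_lag_weights, max_lag = tc$max_lag)
    }
    dat_i <- simulate_deaths(temps_i, sc_i)
    years <- sc_i$start_year + seq_len(sc_i$n_years) - 1L
    cities[[i]] <- daily_city_series(
      sc_i$city_id, sc_i$country, dat_i,
      data.frame(year = years,
                 population = rep(sc_i$annual_population, length(years))))
    scenarios[[i]] <- sc_i
  }
  heat_slopes <- vapply(scenarios, function(s) s$true_curve$heat_log_slope, 0)
  cold_slopes <- vapply(scenarios, function(s) s$true_curve$cold_log_slope, 0)
  truth <- data.frame(
    city_id = vapply(scenarios, `[[`, "", "city_id"),
    mmt_true = vapply(scenarios, function(s) s$true_curve$mmt_true, 0),
    heat_log_slope = heat_slopes, cold_log_slope = cold_slopes)
  structure(list(cities = cities, scenarios = scenarios, truth = truth),
            class = "city_study")
}

#' @export
print.city_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d cities, %d days each\n",
              length(x$cities), nrow(x$cities[[1]]$data)))
  invisible(x)
}

#' Write a study to delimited text files
#'
#' One CSV per city (date, temp_c, deaths columns), a `cities.csv` table
#' (city_id, country, annual_population) and a `truth.json` sidecar with the
#' ground-truth parameters.
#'
#' @param study A `"city_study"` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "city_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in study$cities)
    utils::write.csv(cs$data, file.path(dir, paste0(cs$city_id, ".csv")),
                     row.names = FALSE)
  cities <- data.frame(
    city_id = vapply(study$cities, `[[`, "", "city_id"),
    country = vapply(study$cities, `[[`, "", "country"),
    annual_population = vapply(study$cities,
                               function(cs) cs$population$population[1], 0))
  utils::write.csv(cities, file.path(dir, "cities.csv"), row.names = FALSE)
  truth <- list(
    per_city = study$truth,
    lag_weights = list(
      heat = study$scenarios[[1]]$true_curve$heat_lag_weights,
      cold = study$scenarios[[1]]$true_curve$cold_lag_weights))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `cities.csv` and per-city CSVs.
#' @return A list of [daily_city_series()].
#' @export
read_study <- function(dir) {
  cities <- utils::read.csv(file.path(dir, "cities.csv"))
  lapply(seq_len(nrow(cities)), function(i) {
    d <- utils::read.csv(file.path(dir, paste0(cities$city_id[i], ".csv")))
    d$date <- as.Date(d$date)
    years <- sort(unique(as.integer(format(d$date, "%Y"))))
    daily_city_series(cities$city_id[i], cities$country[i], d,
                      data.frame(year = years,
                                 population = rep(cities$annual_population[i],
                                                  length(years))))
  })
}
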