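# End-to-end orchestration: simulate -> first stage -> second stage -> risk
# summaries -> clustering, as a reproducible, configured, logged run.

#' Build and validate a pipeline run configuration
#'
#' Defaults follow the design this package implements: exposure knots at the
#' 10th/75th/90th percentiles with boundaries at the observed min/max, a
#' 0-21 day lag window, extreme tails at the 5th/95th percentiles, slope
#' percentiles 1/5/95/99, 1000 Monte Carlo draws. Unknown keys are rejected
#' by name.
#'
#' @param ... Overrides for any of: `n_cities`, `n_years`, `template`
#'   (a [city_scenario()]), `heterogeneity`, `master_seed`,
#'   `knot_percentiles`, `max_lag`, `extreme_percentiles`,
#'   `slope_percentiles`, `n_draws`, `country_merge` (named character map),
#'   `cluster_k`, `outcome`, `meta_formula`.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_cities = 20L, n_years = 3L, template = NULL, heterogeneity = 0.005,
    master_seed = 1L,
    knot_percentiles = c(10, 75, 90), max_lag = 21L,
    extreme_percentiles = c(5, 95), slope_percentiles = c(1, 5, 95, 99),
    n_draws = 1000L, country_merge = NULL, cluster_k = 3L,
    outcome = "all", meta_formula = ~ median_temp + temp_range)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_tm("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (nm in c("knot_percentiles", "extreme_percentiles", "slope_percentiles"))
    if (is.unsorted(cfg[[nm]], strictly = TRUE))
      stop_tm("`%s` must be strictly increasing", nm)
  if (cfg$n_draws < 100L) stop_tm("n_draws must be >= 100")
  if (is.null(cfg$template))
    cfg$template <- city_scenario(n_years = cfg$n_years)
  structure(cfg, class = "run_config")
}

#' Merge country labels per a configured map
#'
#' Small country groups (e.g. Central American countries) can be analysed as
#' one category in the meta-regression via a named map
#' `c(original = merged)`.
#'
#' @param countries Character vector of country labels.
#' @param merge_map Named character vector, or `NULL` for no merging.
#' @return Character vector of (possibly merged) labels.
#' @export
merge_countries <- function(countries, merge_map = NULL) {
  if (is.null(merge_map)) return(countries)
  hit <- countries %in% names(merge_map)
  countries[hit] <- unname(merge_map[countries[hit]])
  countries
}

#' Meta-predictor table for a set of city series
#'
#' Median observed daily temperature, temperature range (max minus min of
#' the observed daily means; IQR available as an alternative) and country.
#'
#' @param cities List of [daily_city_series()].
#' @param range_type `"minmax"` (default) or `"iqr"`.
#' @param country_merge Optional country merge map (see
#'   [merge_countries()]).
#' @return `data.frame` with `city_id`, `median_temp`, `temp_range`,
#'   `country`.
#' @export
meta_predictors <- function(cities, range_type = c("minmax", "iqr"),
                            country_merge = NULL) {
  range_type <- match.arg(range_type)
  data.frame(
    city_id = vapply(cities, `[[`, "", "city_id"),
    median_temp = vapply(cities, function(cs)
      empirical_percentile(cs$data$temp_c, 50), 0),
    temp_range = vapply(cities, function(cs) {
      if (range_type == "minmax") diff(range(cs$data$temp_c))
      else diff(empirical_percentile(cs$data$temp_c, c(25, 75)))
    }, 0),
    country = merge_countries(vapply(cities, `[[`, "", "country"),
                              country_merge))
}

#' Run the full two-stage pipeline on a synthetic study
#'
#' Simulates the study, fits every city's conditional Poisson distributed-lag
#' model, reduces to lag-cumulated curves, pools them by REML
#' meta-regression, smooths each city by BLUP, computes per-city and pooled
#' risk summaries, and clusters cities by their temperature distributions.
#' Deterministic given `master_seed`. If `out_dir` is given, writes the
#' artifacts (summary tables, meta-model JSON, cluster table, run manifest)
#' there; stages that fail abort with the failing city named, retaining
#' artifacts already written.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param cities Optional list of [daily_city_series()] to analyse instead
#'   of simulating (the generator stage is then skipped).
#' @param quiet Suppress per-stage log lines?
#' @return List with `study` (if simulated), `fits`, `curves`, `meta`,
#'   `blups`, `summaries` (per-city [risk_summary()] rows), `pooled_edf`,
#'   `pooled_curve`, `clusters` and the `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cities = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- NULL
  if (is.null(cities)) {
    study <- simulate_study(config$n_cities, config$template,
                            heterogeneity = config$heterogeneity,
                            master_seed = config$master_seed)
    cities <- study$cities
    log_("simulated %d cities x %d days", length(cities),
         nrow(cities[[1]]$data))
  }

  fits <- vector("list", length(cities))
  curves <- vector("list", length(cities))
  for (i in seq_along(cities)) {
    cs <- cities[[i]]
    fit <- tryCatch({
      spec <- crossbasis_spec(
        exposure_spec_from_temps(cs$data$temp_c, config$knot_percentiles),
        max_lag = config$max_lag)
      cb <- build_cross_basis(cs$data$temp_c, spec)
      fit_conditional_poisson(cs, cb, outcome = config$outcome)
    }, error = function(e)
      stop_tm("first stage failed for city %s: %s", cs$city_id, conditionMessage(e)))
    fits[[i]] <- fit
    curves[[i]] <- reduce_fit(fit)
  }
  log_("first stage: %d fits, %d converged, %d empty strata dropped in total",
       length(fits), sum(vapply(fits, `[[`, TRUE, "converged")),
       sum(vapply(fits, `[[`, 0L, "n_strata_dropped")))

  preds <- meta_predictors(cities, country_merge = config$country_merge)
  meta <- tryCatch(
    fit_meta_regression(curves, preds, formula = config$meta_formula),
    error = function(e) stop_tm("second stage failed: %s", conditionMessage(e)))
  blups <- lapply(seq_along(cities), function(i)
    blup(meta, curves[[i]], preds[i, , drop = FALSE]))
  log_("second stage: REML logLik %.2f, between-city sds %s",
       meta$logLik_reml, paste(sprintf("%.3f", sqrt(diag(meta$psi))), collapse = "/"))

  summaries <- do.call(rbind, lapply(seq_along(cities), function(i)
    tryCatch(
      risk_summary(blups[[i]], cities[[i]], outcome = config$outcome,
                   n_draws = config$n_draws,
                   seed = config$master_seed + 1000L + i,
                   extreme_percentiles = config$extreme_percentiles,
                   slope_percentiles = config$extreme_percentiles),
      error = function(e)
        stop_tm("risk summary failed for city %s: %s",
                cities[[i]]$city_id, conditionMessage(e)))))
  pooled <- pool_edf(summaries)
  pcurve <- pooled_curve(meta, ref_temp = mean(summaries$mmt))

  grid <- ecdf_grid(lapply(cities, function(cs) cs$data$temp_c))
  feats <- do.call(rbind, lapply(cities, function(cs)
    ecdf_features(cs$data$temp_c, grid)))
  rownames(feats) <- vapply(cities, `[[`, "", "city_id")
  clusters <- ward_cluster(feats, k = min(config$cluster_k, length(cities)))
  log_("clustering: k = %d, sizes %s", clusters$k,
       paste(tabulate(clusters$assignment, clusters$k), collapse = "/"))

  if (!is.null(out_dir)) {
    utils::write.csv(summaries, file.path(out_dir, "risk_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(pooled, file.path(out_dir, "pooled_edf.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(city_id = names(clusters$assignment),
                                cluster = unname(clusters$assignment)),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fixed = meta$fixed, psi = meta$psi,
           predictors = colnames(meta$X), logLik_reml = meta$logLik_reml),
      file.path(out_dir, "meta_model.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    manifest <- list(
      package_version = as.character(utils::packageVersion("tempmort")),
      r_version = R.version.string,
      master_seed = config$master_seed,
      config = config[setdiff(names(config), c("template", "meta_formula"))],
      meta_formula = deparse(config$meta_formula),
      n_cities = length(cities),
      converged = vapply(fits, `[[`, TRUE, "converged"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(list(study = study, fits = fits, curves = curves, meta = meta,
                 blups = blups, summaries = summaries, pooled_edf = pooled,
                 pooled_curve = pcurve, clusters = clusters, config = config))
}
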