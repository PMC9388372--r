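# Grouping cities by their full daily-temperature distributions (empirical
# CDF features + Ward's minimum-variance hierarchical clustering) and fitting
# grouped conditional Poisson models for sparse cause-specific outcomes.

#' Empirical-CDF feature vector of a city's temperatures
#'
#' The empirical cumulative distribution of the city's daily temperatures
#' evaluated on a common grid: the clustering input that captures the full
#' temperature distribution rather than a handful of summaries.
#'
#' @param temps The city's daily temperatures (degrees C).
#' @param grid Ascending grid of temperatures spanning the pooled study
#'   range.
#' @return Numeric vector in `[0, 1]`, one value per grid point,
#'   nondecreasing.
#' @export
ecdf_features <- function(temps, grid) {
  if (!length(temps)) stop_tm("empty temperature series")
  if (is.unsorted(grid, strictly = FALSE)) stop_tm("grid must be ascending")
  stats::ecdf(temps)(grid)
}

#' Common ECDF grid for a set of cities
#'
#' 0.5 degree C steps spanning the pooled min-max across all cities.
#'
#' @param city_temps List of per-city temperature vectors.
#' @param step Grid step in degrees C (default 0.5).
#' @return Ascending numeric grid.
#' @export
ecdf_grid <- function(city_temps, step = 0.5) {
  rng <- range(unlist(lapply(city_temps, range)))
  seq(floor(rng[1] / step) * step, ceiling(rng[2] / step) * step, by = step)
}

#' Ward hierarchical clustering of cities
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances between feature rows, cut at `k` clusters. Rows are
#' ordered by `city_id` before clustering so results are invariant to input
#' order.
#'
#' @param features Numeric matrix, one row per city (e.g. stacked
#'   [ecdf_features()]), with `rownames` giving city ids.
#' @param k Number of clusters (`1 <= k <=` number of cities).
#' @return An object of class `"cluster_assignment"`: `assignment` (named
#'   integer vector city_id -> cluster), `k`, `heights` (merge heights) and
#'   the `hclust` tree.
#' @export
ward_cluster <- function(features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop_tm("k (%d) exceeds the number of cities (%d)", k, n)
  if (k < 1L) stop_tm("k must be >= 1")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("city%03d", seq_len(n))
  features <- features[order(rownames(features)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  structure(list(assignment = assignment, k = as.integer(k),
                 heights = hc$height, tree = hc,
                 feature_grid = colnames(features)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Ward clustering: %d cities in %d cluster(s); sizes %s\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = "/")))
  invisible(x)
}

#' Serialize a cluster tree as nested JSON
#' @param clusters A [ward_cluster()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_json <- function(clusters, path) {
  hc <- clusters$tree
  node <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(node(hc$merge[i, 1]), node(hc$merge[i, 2])))
  }
  jsonlite::write_json(node(nrow(hc$merge)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Fit a grouped conditional Poisson model for one cluster of cities
#'
#' Concatenates the cities' series and fits one conditional Poisson
#' distributed-lag model with strata formed by city x year x month x
#' day-of-week. The exposure spline knots are placed on the pooled
#' within-cluster temperature distribution; cross-bases are built per city
#' (the lag window never crosses a city boundary) and stacked.
#'
#' @param cities List of [daily_city_series()] in one cluster.
#' @param outcome Death-count column (default `"all"`).
#' @param knot_percentiles Exposure knot percentiles on the pooled
#'   within-cluster temperatures (default `c(10, 75, 90)`).
#' @param max_lag Lag window (default 21).
#' @param ... Passed to [fit_conditional_poisson()]'s core (tolerances).
#' @return A `"first_stage_fit"` whose `temps` are the pooled within-cluster
#'   temperatures and whose `city_id` names the cluster members.
#' @export
fit_group_model <- function(cities, outcome = "all",
                            knot_percentiles = c(10, 75, 90), max_lag = 21L,
                            ...) {
  stopifnot(is.list(cities), length(cities) >= 1L)
  lapply(cities, function(cs) stopifnot(inherits(cs, "daily_city_series")))
  cities <- cities[order(vapply(cities, `[[`, "", "city_id"))]
  pooled_temps <- unlist(lapply(cities, function(cs) cs$data$temp_c))
  spec <- crossbasis_spec(exposure_spec_from_temps(pooled_temps, knot_percentiles),
                          max_lag = max_lag)
  col <- if (grepl("^deaths_", outcome)) outcome else paste0("deaths_", outcome)
  d <- c(); X <- NULL; strata <- c(); offset <- c(); use <- c()
  for (cs in cities) {
    cb <- build_cross_basis(cs$data$temp_c, spec)
    nI <- nrow(cs$data)
    yr <- as.integer(format(cs$data$date, "%Y"))
    pop <- cs$population$population[match(yr, cs$population$year)]
    d <- c(d, cs$data[[col]])
    X <- rbind(X, cb$matrix)
    strata <- c(strata, make_strata(cs$data$date, city_id = cs$city_id))
    offset <- c(offset, log(pop))
    use <- c(use, seq_len(nI) > max_lag)        # per-city burn-in
  }
  if (all(d == 0)) stop_tm("outcome `%s` is all zero across the cluster", col)
  core <- fit_cpoisson_core(d[use], X[use, , drop = FALSE], strata[use],
                            offset[use], ...)
  structure(list(city_id = paste(vapply(cities, `[[`, "", "city_id"),
                                 collapse = "+"),
                 coef = core$coef, vcov = core$vcov, loglik = core$loglik,
                 converged = core$converged, dispersion = core$dispersion,
                 n_days_used = core$n_days_used,
                 n_strata_used = core$n_strata_used,
                 n_strata_dropped = core$n_strata_dropped,
                 scale_dispersion = FALSE, spec = spec,
                 temps = pooled_temps, outcome = col),
            class = "first_stage_fit")
}
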