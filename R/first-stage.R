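# City-specific conditional Poisson distributed-lag models.
#
# The stratum intercepts (day-of-week x month x year) are eliminated by
# conditioning on the stratum death totals: the conditional likelihood is the
# multinomial
#   l(beta) = sum_t d_t eta_t - sum_s D_s log sum_{t in s} exp(eta_t),
# numerically identical at the maximum to a Poisson fit with one indicator
# per stratum, but with thousands fewer parameters. Fisher scoring on this
# likelihood converges in a handful of iterations.

#' Stratum labels for conditional Poisson fitting
#'
#' One stratum per (year, month, day-of-week) triple, the full triple
#' cross-classification: days share a stratum only if they fall in the same
#' calendar month of the same year on the same weekday (4-5 days each).
#'
#' @param dates `Date` vector.
#' @param city_id Optional city identifier prefix, for grouped multi-city
#'   models whose strata are city x year x month x day-of-week.
#' @return Character vector of stratum labels, one per day.
#' @export
make_strata <- function(dates, city_id = NULL) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  lab <- sprintf("%04d-%02d-%d", lt$year + 1900L, lt$mon + 1L, lt$wday)
  if (!is.null(city_id)) lab <- paste(city_id, lab, sep = ":")
  lab
}

# Core conditional Poisson maximizer on a prepared design.
# d: counts; X: design; strata: labels; offset: log population (constant
# within strata, so it cancels in the conditional likelihood, but it is kept
# for fidelity to the unconditional parameterization).
fit_cpoisson_core <- function(d, X, strata, offset,
                              tol = 1e-9, max_iter = 100L) {
  keep <- stats::ave(d, strata, FUN = sum) > 0   # zero-total strata carry no information
  n_strata_dropped <- length(unique(strata[!keep]))
  d <- d[keep]; X <- X[keep, , drop = FALSE]
  strata <- strata[keep]; offset <- offset[keep]
  if (!length(d)) stop_tm("no stratum with nonzero total deaths")
  sf <- factor(strata)
  si <- as.integer(sf)
  ns <- nlevels(sf)
  Ds <- drop(rowsum(d, si))                      # stratum death totals
  p <- ncol(X)

  # log-likelihood and derivatives in one pass; per-stratum max-subtraction
  # keeps exp() in range
  eval_fit <- function(beta) {
    eta <- offset + drop(X %*% beta)
    mstrat <- as.vector(tapply(eta, si, max))
    w <- exp(eta - mstrat[si])
    Tw <- drop(rowsum(w, si))
    ll <- sum(d * eta) - sum(Ds * (log(Tw) + mstrat))
    prob <- w / Tw[si]
    mu <- Ds[si] * prob                          # conditional fitted values
    grad <- drop(crossprod(X, d - mu))
    G <- rowsum(X * mu, si)                      # ns x p: X' mu by stratum
    info <- crossprod(X * sqrt(mu)) - crossprod(G / sqrt(Ds))
    list(ll = ll, grad = grad, info = symmetrize(info), mu = mu)
  }

  beta <- numeric(p)
  st <- eval_fit(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(st$info, st$grad), error = function(e)
      solve(st$info + diag(1e-8, p), st$grad))
    new_beta <- beta + step
    new_st <- eval_fit(new_beta)
    halvings <- 0L
    while (!is.finite(new_st$ll) || new_st$ll < st$ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      new_beta <- beta + step
      new_st <- eval_fit(new_beta)
    }
    rel <- abs(new_st$ll - st$ll) / (abs(st$ll) + 1e-10)
    beta <- new_beta; st <- new_st
    if (rel < tol) { converged <- TRUE; break }
  }
  vcov <- tryCatch(symmetrize(solve(st$info)), error = function(e)
    symmetrize(solve(st$info + diag(1e-8, p))))
  pearson <- sum((d - st$mu)^2 / pmax(st$mu, 1e-12))
  df_resid <- max(length(d) - ns - p, 1L)
  list(coef = beta, vcov = vcov, loglik = st$ll, converged = converged,
       iterations = it, dispersion = pearson / df_resid,
       n_days_used = length(d), n_strata_used = ns,
       n_strata_dropped = n_strata_dropped)
}

#' Fit a city-specific conditional Poisson distributed-lag model
#'
#' Maximizes the Poisson likelihood conditional on the death totals of the
#' (year, month, day-of-week) strata — equivalent to a Poisson regression
#' with explicit stratum indicators — with the log annual city population as
#' an offset. The first `max_lag` days (incomplete exposure history) are
#' excluded from the likelihood, and strata with zero total deaths are
#' dropped (they carry no conditional information; the count is reported).
#'
#' @param series A [daily_city_series()].
#' @param crossbasis A [build_cross_basis()] object built from
#'   `series$data$temp_c` (or, for grouped fits, a compatible matrix).
#' @param outcome Name of the death-count column, without or with the
#'   `deaths_` prefix (default `"all"`).
#' @param scale_dispersion If `TRUE`, multiply the covariance by
#'   `max(1, Pearson dispersion)` (quasi-Poisson style). Off by default;
#'   recorded in the result.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @return An object of class `"first_stage_fit"`: coefficients, covariance,
#'   convergence flag, dispersion and bookkeeping counts, plus the
#'   cross-basis spec and the observed temperatures (for later reduction and
#'   percentile work).
#' @export
fit_conditional_poisson <- function(series, crossbasis, outcome = "all",
                                    scale_dispersion = FALSE,
                                    tol = 1e-9, max_iter = 100L) {
  stopifnot(inherits(series, "daily_city_series"),
            inherits(crossbasis, "crossbasis"))
  dat <- series$data
  col <- if (grepl("^deaths_", outcome)) outcome else paste0("deaths_", outcome)
  if (!col %in% names(dat)) stop_tm("no outcome column `%s`", col)
  d <- dat[[col]]
  if (all(d == 0)) stop_tm("outcome `%s` is all zero", col)
  X <- crossbasis$matrix
  if (nrow(X) != nrow(dat)) stop_tm("cross-basis rows != series days")
  L <- crossbasis$spec$max_lag
  use <- seq_len(nrow(dat)) > L                   # burn-in: incomplete history
  strata <- make_strata(dat$date)
  yr <- as.integer(format(dat$date, "%Y"))
  pop <- series$population$population[match(yr, series$population$year)]
  offset <- log(pop)
  core <- fit_cpoisson_core(d[use], X[use, , drop = FALSE], strata[use],
                            offset[use], tol = tol, max_iter = max_iter)
  if (!core$converged)
    warning(sprintf("conditional Poisson fit for %s did not converge in %d iterations",
                    series$city_id, max_iter))
  vcov <- core$vcov
  if (scale_dispersion) vcov <- vcov * max(1, core$dispersion)
  structure(list(city_id = series$city_id, coef = core$coef, vcov = vcov,
                 loglik = core$loglik, converged = core$converged,
                 dispersion = core$dispersion,
                 n_days_used = core$n_days_used,
                 n_strata_used = core$n_strata_used,
                 n_strata_dropped = core$n_strata_dropped,
                 scale_dispersion = scale_dispersion,
                 spec = crossbasis$spec,
                 temps = dat$temp_c, outcome = col),
            class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("conditional Poisson fit [%s, %s]: %d coef, %d days in %d strata (%d empty dropped), %sconverged, dispersion %.2f\n",
              x$city_id, x$outcome, length(x$coef), x$n_days_used,
              x$n_strata_used, x$n_strata_dropped,
              if (x$converged) "" else "NOT ", x$dispersion))
  invisible(x)
}

#' Reduce a first-stage fit to its lag-cumulated curve
#'
#' Convenience wrapper around [reduce_to_overall()]: sums the fitted surface
#' over lags and centres the curve at the city's median observed temperature
#' (recentred at the MMT later, exactly, via [recentre_curve()]).
#'
#' @param fit A [fit_conditional_poisson()] result.
#' @param ref_temp Centering temperature; default the median observed
#'   temperature.
#' @return A [reduced_curve()].
#' @export
reduce_fit <- function(fit, ref_temp = NULL) {
  stopifnot(inherits(fit, "first_stage_fit"))
  if (is.null(ref_temp)) ref_temp <- empirical_percentile(fit$temps, 50)
  reduce_to_overall(fit$coef, fit$vcov, fit$spec, ref_temp)
}

#' Wald test of the full cross-basis coefficient block
#'
#' Chi-square test of `H0: beta = 0` for all cross-basis coefficients, the
#' first-stage check that a city shows any temperature-mortality association.
#'
#' @param fit A [fit_conditional_poisson()] result.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "first_stage_fit"))
  stat <- drop(crossprod(fit$coef, solve(fit$vcov, fit$coef)))
  df <- length(fit$coef)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Serialize a first-stage fit to JSON
#' @param fit A `"first_stage_fit"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "first_stage_fit"))
  jsonlite::write_json(
    list(city_id = fit$city_id, outcome = fit$outcome, coef = fit$coef,
         vcov = fit$vcov, converged = fit$converged,
         dispersion = fit$dispersion, n_days_used = fit$n_days_used,
         n_strata_used = fit$n_strata_used,
         n_strata_dropped = fit$n_strata_dropped),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
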