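#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_tm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_tm("`%s` must be finite numeric", name)
  invisible(x)
}

assert_scalar <- function(x, name) {
  if (length(x) != 1L) stop_tm("`%s` must be a scalar", name)
  assert_finite(x, name)
}

# Symmetrize a matrix that is symmetric up to round-off.
symmetrize <- function(m) (m + t(m)) / 2

# Draws from N(mean, sigma) via the Cholesky factor; consumes the RNG stream.
rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  sigma <- symmetrize(sigma)
  rt <- tryCatch(chol(sigma), error = function(e) {
    # PSD-but-singular covariances (e.g. a collapsed vcov) get an eigen route
    e2 <- eigen(sigma, symmetric = TRUE)
    t(e2$vectors %*% diag(sqrt(pmax(e2$values, 0)), p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% rt, 2L, mean, `+`)
}

# Linear-interpolation empirical quantile (the common statistical default).
#' Empirical percentile of a temperature series
#'
#' Linear-interpolation empirical quantile, the convention used for all
#' percentile thresholds in this package (knot placement, extreme-temperature
#' tails, slope percentiles).
#'
#' @param temps Numeric vector of observations (degrees C).
#' @param p Percentile in `[0, 100]`; may be a vector.
#' @return Numeric vector of the same length as `p`.
#' @examples
#' empirical_percentile(c(1, 2, 3, 4), 50) # 2.5
#' @export
empirical_percentile <- function(temps, p) {
  if (length(temps) == 0L) stop_tm("empty temperature series")
  assert_finite(temps, "temps")
  if (any(p < 0 | p > 100)) stop_tm("percentile must be in [0, 100]")
  unname(stats::quantile(temps, probs = p / 100, type = 7, names = FALSE))
}
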