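# Natural cubic spline bases, the temperature x lag cross-basis, reduction of
# the fitted surface to a lag-cumulated exposure-response curve, and curve
# prediction with delta-method standard errors.

#' Specify a natural cubic spline basis
#'
#' @param boundary_knots Length-2 numeric `(lo, hi)`, in degrees C for the
#'   exposure axis or days for the lag axis. The basis is linear beyond these.
#' @param internal_knots Ascending numeric vector strictly inside the
#'   boundaries. May be empty.
#' @param intercept Should the basis include an intercept column?
#' @param constant If `TRUE`, the basis is a single all-ones column (an
#'   intercept-only basis, e.g. for an unweighted moving-sum lag structure);
#'   `internal_knots` must be empty and `intercept` is implied.
#' @return An object of class `"spline_spec"`. Its dimension (number of basis
#'   columns) is `length(internal_knots) + 1`, plus one if `intercept`;
#'   a `constant` spec has dimension 1.
#' @examples
#' # the default exposure basis of this package: knots at P10/P75/P90,
#' # boundaries at the observed min/max -> 4 columns
#' x <- runif(100, 0, 30)
#' sp <- spline_spec(range(x), empirical_percentile(x, c(10, 75, 90)))
#' spline_dim(sp)
#' @export
spline_spec <- function(boundary_knots, internal_knots = numeric(),
                        intercept = FALSE, constant = FALSE) {
  if (isTRUE(constant)) {
    if (length(internal_knots)) stop_tm("a constant spec takes no internal knots")
    return(structure(list(boundary_knots = as.numeric(boundary_knots),
                          internal_knots = numeric(), intercept = TRUE,
                          constant = TRUE),
                     class = "spline_spec"))
  }
  assert_finite(boundary_knots, "boundary_knots")
  if (length(boundary_knots) != 2L || boundary_knots[1] >= boundary_knots[2])
    stop_tm("boundary_knots must be (lo, hi) with lo < hi")
  if (length(internal_knots)) {
    assert_finite(internal_knots, "internal_knots")
    internal_knots <- sort(internal_knots)
    if (min(internal_knots) <= boundary_knots[1] || max(internal_knots) >= boundary_knots[2])
      stop_tm("internal knots must lie strictly inside the boundary knots")
  }
  structure(list(boundary_knots = as.numeric(boundary_knots),
                 internal_knots = as.numeric(internal_knots),
                 intercept = isTRUE(intercept), constant = FALSE),
            class = "spline_spec")
}

#' Dimension (number of columns) of a spline basis
#' @param spec A [spline_spec()].
#' @return Integer column count.
#' @export
spline_dim <- function(spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (isTRUE(spec$constant)) return(1L)
  length(spec$internal_knots) + 1L + as.integer(spec$intercept)
}

#' Exposure spline spec from an observed temperature series
#'
#' Places internal knots at percentiles of the observed daily temperatures and
#' boundary knots at the observed minimum and maximum. The default percentiles
#' 10/75/90 give a 4-column basis.
#'
#' @param temps Observed daily temperatures (degrees C).
#' @param knot_percentiles Percentiles for the internal knots.
#' @return A [spline_spec()] without intercept.
#' @export
exposure_spec_from_temps <- function(temps, knot_percentiles = c(10, 75, 90)) {
  spline_spec(range(temps), empirical_percentile(temps, knot_percentiles),
              intercept = FALSE)
}

#' Evaluate a natural cubic spline basis
#'
#' Natural cubic splines: cubic between knots, with zero second derivative at
#' and beyond the boundary knots, hence exactly linear outside them. Values of
#' `x` beyond the boundary knots are allowed (linear extrapolation).
#'
#' @param x Numeric values at which to evaluate.
#' @param spec A [spline_spec()].
#' @return `length(x)` x `spline_dim(spec)` numeric matrix.
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  assert_finite(x, "x")
  if (isTRUE(spec$constant))
    return(matrix(1, length(x), 1L, dimnames = list(NULL, "b1")))
  b <- splines::ns(x,
                   knots = if (length(spec$internal_knots)) spec$internal_knots,
                   Boundary.knots = spec$boundary_knots,
                   intercept = spec$intercept)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Specify a temperature x lag cross-basis
#'
#' The cross-basis is the tensor product of a nonlinear exposure basis and a
#' basis over the lag dimension, so one coefficient vector describes the full
#' exposure-lag-response surface. The default lag basis is a natural cubic
#' spline over lags 0..21 with intercept and three internal knots equally
#' spaced on the log(lag + 1) scale (lag dimension 5), the convention of the
#' two-stage multi-city literature.
#'
#' @param exposure_spec [spline_spec()] for the temperature axis (no
#'   intercept; 4 columns under the default knot percentiles).
#' @param max_lag Maximum lag in days (default 21).
#' @param lag_spec [spline_spec()] for the lag axis, or `NULL` for the
#'   default described above.
#' @return An object of class `"crossbasis_spec"`.
#' @export
crossbasis_spec <- function(exposure_spec, max_lag = 21L, lag_spec = NULL) {
  stopifnot(inherits(exposure_spec, "spline_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop_tm("max_lag must be >= 1")
  if (is.null(lag_spec)) {
    ik <- exp(seq(0, log(max_lag + 1), length.out = 5L))[2:4] - 1
    lag_spec <- spline_spec(c(0, max_lag), ik, intercept = TRUE)
  }
  stopifnot(inherits(lag_spec, "spline_spec"))
  structure(list(exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = max_lag),
            class = "crossbasis_spec")
}

#' Build the cross-basis design matrix for a daily exposure series
#'
#' Row `t` of the matrix is `sum_{l=0..max_lag} B(x[t-l]) x C(l)` arranged so
#' that column `(j-1)*lag_dim + k` holds `sum_l B_j(x[t-l]) C_k(l)`: it
#' depends on the exposures at days `t, t-1, ..., t-max_lag` only. The first
#' `max_lag` rows use backward-padded exposure (the series' first value);
#' model fitting drops them as burn-in.
#'
#' @param temps Daily exposure series (degrees C), length > `max_lag`.
#' @param spec A [crossbasis_spec()].
#' @return An object of class `"crossbasis"`: list with the `matrix`, the
#'   `spec` and the `exposure_series`.
#' @export
build_cross_basis <- function(temps, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  assert_finite(temps, "temps")
  n <- length(temps)
  L <- spec$max_lag
  if (n <= L) stop_tm("series length (%d) must exceed max_lag (%d)", n, L)
  vx <- spline_dim(spec$exposure_spec)
  vl <- spline_dim(spec$lag_spec)
  C <- natural_cubic_basis(0:L, spec$lag_spec)     # (L+1) x vl
  W <- matrix(0, n, vx * vl)
  padded <- c(rep(temps[1], L), temps)             # back-fill pre-series days
  for (l in 0:L) {
    Bl <- natural_cubic_basis(padded[(L - l + 1):(L - l + n)], spec$exposure_spec)
    # accumulate B_j(x_{t-l}) * C_k(l) into column (j-1)*vl + k
    W <- W + Bl[, rep(seq_len(vx), each = vl), drop = FALSE] *
      rep(C[l + 1L, ], times = vx)[col(W)]
  }
  colnames(W) <- paste0("v", rep(seq_len(vx), each = vl), ".l", rep(seq_len(vl), vx))
  structure(list(matrix = W, spec = spec, exposure_series = as.numeric(temps)),
            class = "crossbasis")
}

# The 1 x (vx*vl) -> vx reduction matrix summing the lag basis over integer
# lags 0..max_lag, matching the column ordering of build_cross_basis().
lag_sum_matrix <- function(spec) {
  vx <- spline_dim(spec$exposure_spec)
  vl <- spline_dim(spec$lag_spec)
  s <- colSums(natural_cubic_basis(0:spec$max_lag, spec$lag_spec))
  M <- matrix(0, vx, vx * vl)
  for (j in seq_len(vx)) M[j, (j - 1L) * vl + seq_len(vl)] <- s
  M
}

#' Construct a lag-cumulated (reduced) exposure-response curve
#'
#' @param coef Length-`vx` reduced coefficients (one per exposure basis
#'   column).
#' @param vcov `vx` x `vx` covariance matrix.
#' @param exposure_spec The exposure [spline_spec()].
#' @param ref_temp Centering temperature (degrees C): the predicted log-RR at
#'   `ref_temp` is 0 exactly.
#' @return An object of class `"reduced_curve"`.
#' @export
reduced_curve <- function(coef, vcov, exposure_spec, ref_temp) {
  stopifnot(inherits(exposure_spec, "spline_spec"))
  vx <- spline_dim(exposure_spec)
  coef <- as.numeric(coef)
  if (length(coef) != vx) stop_tm("coef length %d != basis dimension %d", length(coef), vx)
  vcov <- symmetrize(as.matrix(vcov))
  if (!all(dim(vcov) == vx)) stop_tm("vcov must be %d x %d", vx, vx)
  assert_scalar(ref_temp, "ref_temp")
  structure(list(coef = coef, vcov = vcov, exposure_spec = exposure_spec,
                 ref_temp = as.numeric(ref_temp)),
            class = "reduced_curve")
}

#' Reduce a fitted cross-basis surface to its lag-cumulated curve
#'
#' Sums the fitted exposure-lag surface over integer lags `0..max_lag`,
#' yielding the overall exposure-response curve on the reduced coefficient
#' scale: `coef_red = M coef`, `vcov_red = M vcov M'` where `M` sums the lag
#' basis across lags.
#'
#' @param coef Full cross-basis coefficient vector.
#' @param vcov Full coefficient covariance.
#' @param spec The [crossbasis_spec()] the coefficients belong to.
#' @param ref_temp Centering temperature for the reduced curve.
#' @return A [reduced_curve()].
#' @export
reduce_to_overall <- function(coef, vcov, spec, ref_temp) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  vx <- spline_dim(spec$exposure_spec)
  vl <- spline_dim(spec$lag_spec)
  coef <- as.numeric(coef)
  if (length(coef) != vx * vl)
    stop_tm("coef length %d != %d x %d cross-basis", length(coef), vx, vl)
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == vx * vl)) stop_tm("vcov dimensions do not match coef")
  M <- lag_sum_matrix(spec)
  reduced_curve(drop(M %*% coef), symmetrize(M %*% vcov %*% t(M)),
                spec$exposure_spec, ref_temp)
}

#' Recentre a reduced curve at a new reference temperature
#'
#' Exact via basis-difference algebra: only the stored reference changes; all
#' predicted contrasts are unaffected.
#'
#' @param curve A [reduced_curve()].
#' @param ref_temp New centering temperature (degrees C).
#' @return The recentred [reduced_curve()].
#' @export
recentre_curve <- function(curve, ref_temp) {
  stopifnot(inherits(curve, "reduced_curve"))
  reduced_curve(curve$coef, curve$vcov, curve$exposure_spec, ref_temp)
}

#' Predict log-relative-risk along a reduced curve
#'
#' Computes `logRR(x) = (B(x) - B(ref)) coef` with pointwise delta-method
#' standard errors from the curve covariance. `logRR(ref_temp) = 0` with zero
#' standard error, by construction.
#'
#' @param curve A [reduced_curve()].
#' @param temps Temperatures (degrees C) at which to predict.
#' @return `data.frame` with columns `temp`, `logrr`, `se`, `rr`, `rr_low`,
#'   `rr_high` (95\% interval, `exp(logrr +/- 1.96 se)`).
#' @export
predict_curve <- function(curve, temps) {
  stopifnot(inherits(curve, "reduced_curve"))
  X <- centred_basis(curve, temps)
  logrr <- drop(X %*% curve$coef)
  se <- sqrt(pmax(rowSums((X %*% curve$vcov) * X), 0))
  data.frame(temp = as.numeric(temps), logrr = logrr, se = se,
             rr = exp(logrr),
             rr_low = exp(logrr - 1.96 * se),
             rr_high = exp(logrr + 1.96 * se))
}

# Basis differences B(x) - B(ref_temp): the design for all curve contrasts.
centred_basis <- function(curve, temps) {
  B <- natural_cubic_basis(as.numeric(temps), curve$exposure_spec)
  Bref <- natural_cubic_basis(curve$ref_temp, curve$exposure_spec)
  sweep(B, 2L, drop(Bref), `-`)
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("natural cubic spline: boundaries [%.3g, %.3g], %d internal knot(s)%s, dim %d\n",
              x$boundary_knots[1], x$boundary_knots[2],
              length(x$internal_knots),
              if (x$intercept) ", with intercept" else "",
              spline_dim(x)))
  invisible(x)
}

#' @export
print.crossbasis_spec <- function(x, ...) {
  cat(sprintf("cross-basis spec: exposure dim %d x lag dim %d (lags 0..%d) = %d columns\n",
              spline_dim(x$exposure_spec), spline_dim(x$lag_spec), x$max_lag,
              spline_dim(x$exposure_spec) * spline_dim(x$lag_spec)))
  invisible(x)
}

#' @export
print.reduced_curve <- function(x, ...) {
  cat(sprintf("lag-cumulated exposure-response curve: %d coefficients, centred at %.2f C\n",
              length(x$coef), x$ref_temp))
  invisible(x)
}

#' Serialize a spline or cross-basis spec to JSON
#' @param spec A [spline_spec()] or [crossbasis_spec()].
#' @return JSON string.
#' @export
spec_to_json <- function(spec) {
  if (inherits(spec, "spline_spec")) {
    jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  } else if (inherits(spec, "crossbasis_spec")) {
    jsonlite::toJSON(list(exposure_spec = unclass(spec$exposure_spec),
                          lag_spec = unclass(spec$lag_spec),
                          max_lag = spec$max_lag),
                     auto_unbox = TRUE, digits = NA)
  } else stop_tm("not a spec object")
}
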