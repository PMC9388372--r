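# Multivariate random-effects meta-regression across cities.
#
# Model: y_i ~ N(Theta' x_i, S_i + Psi), where y_i are a city's k reduced
# spline coefficients, S_i its within-city covariance, x_i its meta-predictor
# row and Psi the unstructured k x k between-city covariance. Psi is
# estimated by REML, parameterized through its Cholesky factor so it stays
# positive semidefinite; the fixed effects Theta are profiled out by GLS at
# each Psi, so the optimizer works on the k(k+1)/2 Psi parameters only.

# Map an unconstrained parameter vector to a lower-triangular Cholesky
# factor (log-parameterized diagonal).
par_to_chol <- function(par, k) {
  Lm <- matrix(0, k, k)
  Lm[lower.tri(Lm, diag = TRUE)] <- par
  diag(Lm) <- exp(diag(Lm))
  Lm
}

chol_to_par <- function(Lm) {
  d <- diag(Lm)
  diag(Lm) <- log(pmax(d, 1e-12))
  Lm[lower.tri(Lm, diag = TRUE)]
}

# Restricted log-likelihood with Theta profiled out, plus the GLS pieces.
reml_pieces <- function(psi, y, S, X) {
  k <- ncol(y); m <- nrow(y); q <- ncol(X)
  XtVX <- matrix(0, k * q, k * q)
  XtVy <- numeric(k * q)
  Vinv <- vector("list", m)
  for (i in seq_len(m)) {
    Vi <- S[[i]] + psi
    Vinv_i <- tryCatch(chol2inv(chol(Vi)), error = function(e) NULL)
    if (is.null(Vinv_i)) return(NULL)
    Vinv[[i]] <- Vinv_i
    Xi <- kronecker(matrix(X[i, ], 1, q), diag(k))  # k x kq
    XtVX <- XtVX + crossprod(Xi, Vinv_i %*% Xi)
    XtVy <- XtVy + drop(crossprod(Xi, Vinv_i %*% y[i, ]))
  }
  theta_v <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(theta_v)) return(NULL)
  ll <- 0
  for (i in seq_len(m)) {
    Vi <- S[[i]] + psi
    Xi <- kronecker(matrix(X[i, ], 1, q), diag(k))
    r <- y[i, ] - drop(Xi %*% theta_v)
    ld <- determinant(Vi, logarithm = TRUE)$modulus
    ll <- ll - 0.5 * (ld + drop(crossprod(r, Vinv[[i]] %*% r)))
  }
  ll <- ll - 0.5 * determinant(XtVX, logarithm = TRUE)$modulus
  list(reml = as.numeric(ll), theta = theta_v, XtVX = XtVX)
}

#' Fit a multivariate random-effects meta-regression of reduced curves
#'
#' Pools city-specific lag-cumulated spline coefficients with restricted
#' maximum likelihood, estimating fixed effects for the meta-predictors and
#' an unstructured between-city covariance `psi`. The default predictors
#' mirror the two-stage design this package implements: each city's median
#' observed daily temperature, its temperature range, and country.
#'
#' All supplied curves must share the same exposure spline and reference
#' temperature convention is per-city (coefficients, not centred predictions,
#' are pooled, so per-city reference temperatures are immaterial).
#'
#' @param curves List of [reduced_curve()] objects, one per city.
#' @param predictors `data.frame` with one row per city; variables referenced
#'   by `formula`. May be `NULL` with `formula = ~ 1` (intercept only).
#' @param formula Right-hand-side formula for the meta-predictors (default
#'   `~ median_temp + temp_range + country`).
#' @param psi_fixed Optionally fix `psi` instead of estimating it (for
#'   common-effect pooling use a zero matrix).
#' @param max_iter,reltol Optimizer control.
#' @return An object of class `"meta_model"`: `fixed` (q x k matrix),
#'   `vcov_fixed` (kq x kq, from the REML information), `psi`, `logLik_reml`,
#'   `converged`, plus the design pieces needed for prediction and BLUP.
#' @export
fit_meta_regression <- function(curves, predictors = NULL,
                                formula = ~ median_temp + temp_range + country,
                                psi_fixed = NULL,
                                max_iter = 500L, reltol = 1e-12) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  lapply(curves, function(cu) stopifnot(inherits(cu, "reduced_curve")))
  k <- length(curves[[1]]$coef)
  y <- t(vapply(curves, `[[`, numeric(k), "coef"))
  S <- lapply(curves, function(cu) {
    v <- symmetrize(cu$vcov)
    if (inherits(tryCatch(chol(v), error = function(e) e), "error"))
      stop_tm("singular within-city vcov for city curve `%s`",
              if (!is.null(cu$city_id)) cu$city_id else "<unnamed>")
    v
  })
  m <- length(curves)
  if (is.null(predictors)) predictors <- data.frame(row.names = seq_len(m))
  X <- stats::model.matrix(formula, data = predictors)
  if (nrow(X) != m) stop_tm("predictors rows (%d) != number of curves (%d)", nrow(X), m)
  q <- ncol(X)
  if (m < q + 2L) stop_tm("need at least %d cities for %d predictor terms", q + 2L, q)

  if (!is.null(psi_fixed)) {
    psi <- symmetrize(as.matrix(psi_fixed))
    pieces <- reml_pieces(psi, y, S, X)
    if (is.null(pieces)) stop_tm("supplied psi yields a singular marginal covariance")
    conv <- TRUE
  } else {
    # start from the residual moment estimate of psi, floored to PSD
    fe0 <- reml_pieces(matrix(0, k, k), y, S, X)
    if (is.null(fe0)) stop_tm("fixed-effects start failed; check within-city vcovs")
    res <- y - t(vapply(seq_len(m), function(i)
      drop(kronecker(matrix(X[i, ], 1, q), diag(k)) %*% fe0$theta), numeric(k)))
    psi0 <- stats::cov(res) - Reduce(`+`, S) / m
    e0 <- eigen(symmetrize(psi0), symmetric = TRUE)
    psi0 <- e0$vectors %*% diag(pmax(e0$values, 1e-4), k) %*% t(e0$vectors)
    par0 <- chol_to_par(t(chol(symmetrize(psi0))))
    negreml <- function(par) {
      Lm <- par_to_chol(par, k)
      p <- reml_pieces(tcrossprod(Lm), y, S, X)
      if (is.null(p) || !is.finite(p$reml)) return(1e10)
      -p$reml
    }
    opt <- stats::optim(par0, negreml, method = "BFGS",
                        control = list(maxit = max_iter, reltol = reltol))
    if (opt$convergence != 0L) {
      # polish from the BFGS iterate with a derivative-free pass
      opt2 <- stats::optim(opt$par, negreml, method = "Nelder-Mead",
                           control = list(maxit = 2000L, reltol = reltol))
      if (opt2$value <= opt$value) opt <- opt2
    }
    Lm <- par_to_chol(opt$par, k)
    psi <- symmetrize(tcrossprod(Lm))
    pieces <- reml_pieces(psi, y, S, X)
    conv <- opt$convergence == 0L && !is.null(pieces)
    if (!conv) warning("meta-regression REML did not converge")
  }
  fixed <- matrix(pieces$theta, nrow = q, ncol = k, byrow = TRUE,
                  dimnames = list(colnames(X), paste0("b", seq_len(k))))
  vcov_fixed <- tryCatch(symmetrize(solve(pieces$XtVX)), error = function(e)
    symmetrize(solve(pieces$XtVX + diag(1e-10, k * q))))
  structure(list(fixed = fixed, vcov_fixed = vcov_fixed, psi = psi,
                 logLik_reml = pieces$reml, converged = conv,
                 formula = formula, predictors = predictors, X = X,
                 k = k, exposure_spec = curves[[1]]$exposure_spec,
                 curves = curves),
            class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("multivariate meta-regression: %d cities, %d outcomes, %d predictor term(s); REML logLik %.2f%s\n",
              nrow(x$X), x$k, ncol(x$X), x$logLik_reml,
              if (x$converged) "" else " (NOT converged)"))
  cat("between-city sd (sqrt diag psi):",
      paste(sprintf("%.4f", sqrt(diag(x$psi))), collapse = " "), "\n")
  invisible(x)
}

# Fixed-effects prediction design row for one city, with categorical
# predictors expanded against the training levels.
meta_design_row <- function(model, newdata) {
  pr <- model$predictors
  need <- setdiff(all.vars(model$formula), names(newdata))
  if (length(need))
    stop_tm("missing predictor column(s) in newdata: %s",
            paste(need, collapse = ", "))
  for (nm in names(pr)) {
    if ((is.character(pr[[nm]]) || is.factor(pr[[nm]])) && nm %in% names(newdata))
      newdata[[nm]] <- factor(newdata[[nm]], levels = levels(factor(pr[[nm]])))
  }
  X1 <- stats::model.matrix(model$formula, data = newdata)
  if (!identical(colnames(X1), colnames(model$X)))
    stop_tm("predictor columns do not match the fitted model (%s vs %s)",
            paste(colnames(X1), collapse = ","), paste(colnames(model$X), collapse = ","))
  X1
}

#' Best linear unbiased prediction of a city's curve
#'
#' Shrinks a city's first-stage curve toward its meta-regression prediction
#' in proportion to the city's statistical imprecision:
#' `blup = pred + psi (psi + S_i)^{-1} (y_i - pred)`, with conditional
#' covariance `psi - psi (psi + S_i)^{-1} psi` (fixed-effect uncertainty in
#' the prediction is not propagated; this is the usual smoothed-curve
#' variant).
#'
#' @param model A fitted [fit_meta_regression()].
#' @param curve The city's first-stage [reduced_curve()].
#' @param newdata One-row `data.frame` of the city's meta-predictors.
#' @return A [reduced_curve()] with the BLUP coefficients and conditional
#'   covariance, centred at the input curve's reference temperature.
#' @export
blup <- function(model, curve, newdata = NULL) {
  stopifnot(inherits(model, "meta_model"), inherits(curve, "reduced_curve"))
  k <- model$k
  if (is.null(newdata)) newdata <- data.frame(row.names = 1L)
  X1 <- meta_design_row(model, newdata)
  pred <- drop(X1 %*% model$fixed)
  A <- model$psi + symmetrize(curve$vcov)
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
    chol2inv(chol(A + diag(1e-12, k))))
  gain <- model$psi %*% Ainv                     # psi (psi + S_i)^-1
  co <- pred + drop(gain %*% (curve$coef - pred))
  cond_vcov <- symmetrize(model$psi - gain %*% model$psi)
  reduced_curve(co, cond_vcov, curve$exposure_spec, curve$ref_temp)
}

#' Pooled (fixed-effects) curve at given meta-predictor values
#'
#' The overall exposure-response implied by the meta-regression at a chosen
#' predictor point, with delta-method covariance from the fixed-effects
#' covariance. By default the pooling point is the estimation-sample mean of
#' the design matrix (continuous predictors at their means, country at the
#' sample mix).
#'
#' @param model A fitted [fit_meta_regression()].
#' @param newdata One-row `data.frame` of predictor values, or `NULL` for the
#'   sample-average design row.
#' @param ref_temp Centering temperature for the returned curve.
#' @param exposure_spec Exposure [spline_spec()] on which to interpret the
#'   pooled coefficients. City-specific first-stage bases put knots at each
#'   city's own temperature percentiles, so pooled coefficients describe an
#'   average city on that percentile scale; the default prediction basis is
#'   therefore the element-wise average of the cities' knot and boundary
#'   positions (see [average_exposure_spec()]).
#' @return A [reduced_curve()].
#' @export
pooled_curve <- function(model, newdata = NULL, ref_temp = 0,
                         exposure_spec = NULL) {
  stopifnot(inherits(model, "meta_model"))
  k <- model$k; q <- ncol(model$X)
  if (is.null(exposure_spec))
    exposure_spec <- average_exposure_spec(lapply(model$curves, `[[`, "exposure_spec"))
  x1 <- if (is.null(newdata)) colMeans(model$X) else drop(meta_design_row(model, newdata))
  co <- drop(crossprod(model$fixed, x1))         # k-vector
  Xi <- kronecker(matrix(x1, 1, q), diag(k))
  vc <- symmetrize(Xi %*% model$vcov_fixed %*% t(Xi))
  reduced_curve(co, vc, exposure_spec, ref_temp)
}

#' Average exposure basis across cities
#'
#' Element-wise mean of boundary and internal knot positions across a list
#' of structurally identical [spline_spec()]s: the "average city" basis on
#' which pooled coefficients are interpreted.
#'
#' @param specs List of [spline_spec()]s with equal dimension.
#' @return A [spline_spec()].
#' @export
average_exposure_spec <- function(specs) {
  stopifnot(length(specs) >= 1L)
  dims <- vapply(specs, spline_dim, 0L)
  if (length(unique(dims)) != 1L)
    stop_tm("exposure specs differ in dimension; cannot average")
  spline_spec(
    rowMeans(vapply(specs, `[[`, numeric(2L), "boundary_knots")),
    if (length(specs[[1]]$internal_knots))
      rowMeans(vapply(specs, `[[`,
                      numeric(length(specs[[1]]$internal_knots)),
                      "internal_knots")),
    intercept = specs[[1]]$intercept)
}

#' BLUP curves for every city in a fitted meta-regression
#'
#' @param model A fitted [fit_meta_regression()].
#' @return List of [reduced_curve()]s in the order the curves were supplied.
#' @export
blup_all <- function(model) {
  stopifnot(inherits(model, "meta_model"))
  lapply(seq_along(model$curves), function(i)
    blup(model, model$curves[[i]],
         if (ncol(model$predictors)) model$predictors[i, , drop = FALSE] else NULL))
}
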