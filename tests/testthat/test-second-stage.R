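test_that("identical cities with psi = 0 pool to the common coefficient", {
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  co <- c(0.1, -0.05, 0.2, 0.15)
  curves <- replicate(5, reduced_curve(co, diag(0.02^2, 4), sp, 15),
                      simplify = FALSE)
  mm <- fit_meta_regression(curves, formula = ~ 1,
                            psi_fixed = matrix(0, 4, 4))
  expect_equal(drop(mm$fixed), co, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("psi = 0 with equal covariances reduces to the arithmetic mean", {
  set.seed(5)
  S <- diag(0.03^2, 4)
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  ys <- replicate(6, rnorm(4, c(0.1, 0, 0.2, 0.1), 0.05))
  curves <- lapply(seq_len(6), function(i) reduced_curve(ys[, i], S, sp, 15))
  mm <- fit_meta_regression(curves, formula = ~ 1,
                            psi_fixed = matrix(0, 4, 4))
  expect_lt(max(abs(drop(mm$fixed) - rowMeans(ys))), 1e-8)
})

test_that("REML matches an independent multivariate meta-analysis oracle", {
  skip_if_not_installed("metafor")
  set.seed(42)
  m <- 5
  S_list <- replicate(m, {
    A <- matrix(rnorm(16, 0, 0.02), 4)
    crossprod(A) + diag(0.02^2, 4)
  }, simplify = FALSE)
  curves <- make_meta_curves(m, S_list = S_list, seed = 42)
  mm <- fit_meta_regression(curves, formula = ~ 1)
  yi <- unlist(lapply(curves, `[[`, "coef"))
  V <- matrix(0, 4 * m, 4 * m)
  for (i in seq_len(m))
    V[(4 * i - 3):(4 * i), (4 * i - 3):(4 * i)] <- S_list[[i]]
  dat <- data.frame(yi = yi, outcome = factor(rep(1:4, m)),
                    study = rep(seq_len(m), each = 4))
  rf <- metafor::rma.mv(yi, V, mods = ~ outcome - 1,
                        random = ~ outcome | study, struct = "UN",
                        data = dat, method = "REML",
                        control = list(iter.max = 1000, rel.tol = 1e-10))
  expect_equal(drop(mm$fixed), unname(coef(rf)), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(sqrt(diag(mm$psi)), unname(sqrt(rf$tau2)), tolerance = 1e-2)
})

test_that("between-city standard deviations are recovered by REML", {
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    curves <- make_meta_curves(40, tau = 0.05, seed = 4000 + r)
    mm <- fit_meta_regression(curves, formula = ~ 1)
    sds <- sqrt(diag(mm$psi))
    hits <- hits + all(sds >= 0.03 & sds <= 0.07)
  }
  expect_gte(hits, 8L)
})

test_that("BLUP has the correct limiting behavior", {
  curves <- make_meta_curves(10, tau = 0.05, seed = 17)
  mm <- fit_meta_regression(curves, formula = ~ 1)
  sp <- curves[[1]]$exposure_spec
  pred <- drop(mm$fixed)
  # vanishing within-city vcov: BLUP -> the city's own coefficients
  tight <- reduced_curve(c(0.3, 0.1, -0.2, 0.4), diag(1e-14, 4), sp, 15)
  expect_lt(max(abs(blup(mm, tight)$coef - tight$coef)), 1e-6)
  # enormous within-city vcov: BLUP -> the meta-regression prediction
  vague <- reduced_curve(c(5, -5, 5, -5), diag(1e10, 4), sp, 15)
  expect_lt(max(abs(blup(mm, vague)$coef - pred)), 1e-6)
})

test_that("BLUP lies between the city estimate and the meta prediction", {
  set.seed(23)
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  for (trial in 1:20) {
    psi <- diag(runif(4, 0.01, 0.1)^2)
    S <- diag(runif(4, 0.01, 0.1)^2)
    curves <- make_meta_curves(8, tau = 0.05, seed = 500 + trial)
    mm <- fit_meta_regression(curves, formula = ~ 1, psi_fixed = psi)
    pred <- drop(mm$fixed)
    y <- rnorm(4, pred, 0.2)
    bl <- blup(mm, reduced_curve(y, S, sp, 15))$coef
    # with diagonal psi and S the BLUP is a coordinate-wise convex combination
    lo <- pmin(y, pred) - 1e-10
    hi <- pmax(y, pred) + 1e-10
    expect_true(all(bl >= lo & bl <= hi))
  }
})

test_that("inflating a city's vcov shrinks its BLUP toward the pool", {
  curves <- make_meta_curves(10, tau = 0.05, seed = 29)
  mm <- fit_meta_regression(curves, formula = ~ 1)
  pred <- drop(mm$fixed)
  psi_inv <- solve(mm$psi + diag(1e-12, 4))
  maha <- function(v) drop(crossprod(v - pred, psi_inv %*% (v - pred)))
  y <- curves[[1]]$coef
  S <- curves[[1]]$vcov
  sp <- curves[[1]]$exposure_spec
  d_prev <- Inf
  for (lambda in c(1, 2, 5, 20, 100)) {
    bl <- blup(mm, reduced_curve(y, lambda * S, sp, 15))$coef
    d <- maha(bl)
    expect_lte(d, d_prev + 1e-10)
    d_prev <- d
  }
})

test_that("meta-predictors steer the fixed-effects prediction affinely", {
  set.seed(31)
  m <- 12
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  med <- runif(m, 10, 25)
  slope_fx <- c(0.01, -0.005, 0.02, 0.002)
  curves <- lapply(seq_len(m), function(i)
    reduced_curve(c(0.1, 0, 0.2, 0.1) + slope_fx * med[i] +
                    rnorm(4, 0, 0.001),
                  diag(0.02^2, 4), sp, 15))
  preds <- data.frame(median_temp = med)
  mm <- fit_meta_regression(curves, preds, formula = ~ median_temp)
  p1 <- pooled_curve(mm, data.frame(median_temp = 12), exposure_spec = sp)
  p2 <- pooled_curve(mm, data.frame(median_temp = 20), exposure_spec = sp)
  p3 <- pooled_curve(mm, data.frame(median_temp = 16), exposure_spec = sp)
  expect_equal(p3$coef, (p1$coef + p2$coef) / 2, tolerance = 1e-8)
  # categorical predictors expand against training levels
  preds2 <- data.frame(median_temp = med,
                       country = rep(c("A", "B", "C"), each = 4))
  mm2 <- fit_meta_regression(curves, preds2,
                             formula = ~ median_temp + country)
  expect_error(pooled_curve(mm2, data.frame(median_temp = 15)),
               "missing predictor")
  ok <- pooled_curve(mm2, data.frame(median_temp = 15, country = "B"),
                     exposure_spec = sp)
  expect_identical(length(ok$coef), 4L)
})

test_that("pooled-curve covariance matches Monte Carlo over fixed-effect draws", {
  curves <- make_meta_curves(15, tau = 0.04, seed = 37)
  mm <- fit_meta_regression(curves, formula = ~ 1)
  pc <- pooled_curve(mm)
  set.seed(99)
  draws <- tempmort:::rmvnorm_chol(100000, as.vector(t(mm$fixed)),
                                   mm$vcov_fixed)
  B <- tempmort:::centred_basis(pc, 25)
  mc_sd <- sd(drop(draws %*% drop(B)))
  expect_lt(abs(mc_sd - predict_curve(pc, 25)$se) / mc_sd, 0.02)
})

test_that("degenerate meta inputs are rejected with the city named", {
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  good <- make_meta_curves(6, seed = 3)
  bad <- c(good[1:5],
           list(reduced_curve(c(0.1, 0, 0, 0), matrix(0, 4, 4), sp, 15)))
  expect_error(fit_meta_regression(bad, formula = ~ 1), "singular")
  expect_error(fit_meta_regression(good[1:2],
                                   data.frame(median_temp = 1:2,
                                              temp_range = 2:3,
                                              country = c("A", "B"))),
               "at least")
})
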