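# An independent re-implementation of the attribution loop, used as the
# brute-force oracle throughout this file.
edf_loop_oracle <- function(curve, series, mmt, component, outcome = "all") {
  temps <- series$data$temp_c
  col <- paste0("deaths_", outcome)
  p <- empirical_percentile(temps, c(5, 95))
  cmmt <- recentre_curve(curve, mmt)
  ad <- 0
  for (t in seq_along(temps)) {
    x <- temps[t]
    in_set <- switch(component,
                     heat = x > mmt, cold = x < mmt,
                     extreme_heat = x >= p[2], extreme_cold = x <= p[1],
                     total = x != mmt)
    if (in_set)
      ad <- ad + (1 - exp(-predict_curve(cmmt, x)$logrr)) *
        series$data[[col]][t]
  }
  list(attributable_deaths = ad,
       edf_pct = 100 * ad / sum(series$data[[col]]))
}

test_that("MMT is the argmin over observed temperatures", {
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  # convex curve with vertex at an observed value: quadratic-like in basis
  obs <- seq(0, 30, by = 0.5)
  B <- natural_cubic_basis(obs, sp)
  target <- (obs - 18)^2 / 100
  co <- qr.coef(qr(cbind(1, B)), target)[-1]
  curve <- reduced_curve(co, diag(1e-6, 4), sp, 15)
  got <- find_mmt(curve, obs)
  # the spline approximation of the parabola attains its min at the vertex
  expect_lt(abs(got - 18), 0.51)
  # monotone decreasing curve: boundary MMT at the max observed temperature
  dec <- qr.coef(qr(cbind(1, B)), -obs)[-1]
  expect_identical(find_mmt(reduced_curve(dec, diag(1e-6, 4), sp, 15), obs),
                   max(obs))
  # matches exhaustive evaluation via an independent loop
  set.seed(11)
  for (trial in 1:10) {
    co_r <- rnorm(4, 0, 0.3)
    cu <- reduced_curve(co_r, diag(1e-6, 4), sp, 15)
    obs_r <- runif(200, 0, 30)
    best <- obs_r[1]; best_val <- Inf
    for (x in sort(unique(obs_r))) {
      v <- predict_curve(cu, x)$logrr
      if (v < best_val) { best_val <- v; best <- x }
    }
    expect_identical(find_mmt(cu, obs_r), best)
  }
})

test_that("flat curves attribute nothing", {
  cs <- make_test_city(n_years = 1, seed = 19)
  sp <- exposure_spec_from_temps(cs$data$temp_c)
  flat <- reduced_curve(rep(0, 4), diag(1e-8, 4), sp, 20)
  for (cm in c("total", "heat", "cold", "extreme_heat", "extreme_cold")) {
    af <- attributable_fraction(flat, cs, mmt = 20, component = cm)
    expect_identical(af$attributable_deaths, 0)
    expect_identical(af$edf_pct, 0)
  }
})

test_that("single-day attribution arithmetic is exact", {
  # one day above the MMT at RR = 2 with 10 deaths; 1000 deaths in total
  dates <- seq(as.Date("2010-01-01"), by = "day", length.out = 100)
  temps <- c(rep(10, 99), 25)
  deaths <- c(rep(10, 99), 10)
  stopifnot(sum(deaths) == 1000)
  series <- daily_city_series("toy", "X",
                              data.frame(date = dates, temp_c = temps,
                                         deaths_all = deaths),
                              data.frame(year = 2010, population = 1000))
  sp <- spline_spec(c(5, 30), c(12, 18, 22))
  # solve for coefficients putting logRR(25) - logRR(10) = log 2
  B <- natural_cubic_basis(c(10, 25), sp)
  co <- qr.coef(qr(t(t(B[2, , drop = FALSE] - B[1, , drop = FALSE]))),
                log(2))
  co[is.na(co)] <- 0
  curve <- reduced_curve(co, diag(1e-10, 4), sp, ref_temp = 10)
  af <- attributable_fraction(curve, series, mmt = 10, component = "heat")
  expect_equal(af$attributable_deaths, (1 - 1 / 2) * 10, tolerance = 1e-9)
  expect_equal(af$edf_pct, 0.5, tolerance = 1e-9)
})

test_that("attribution requires a curve centred at the MMT", {
  cs <- make_test_city(n_years = 1, seed = 23)
  sp <- exposure_spec_from_temps(cs$data$temp_c)
  curve <- reduced_curve(c(0.2, 0.1, 0.3, 0.2), diag(1e-4, 4), sp,
                         ref_temp = empirical_percentile(cs$data$temp_c, 50))
  mmt <- find_mmt(curve, cs$data$temp_c)
  expect_error(attributable_fraction(curve, cs, mmt), "recentred")
  expect_silent(attributable_fraction(recentre_curve(curve, mmt), cs, mmt))
})

test_that("attribution matches the day-by-day loop oracle", {
  cs <- make_test_city(n_years = 2, seed = 27)
  fit <- fit_conditional_poisson(cs, make_test_crossbasis(cs$data$temp_c))
  curve <- reduce_fit(fit)
  mmt <- find_mmt(curve, cs$data$temp_c)
  cmmt <- recentre_curve(curve, mmt)
  for (cm in c("total", "heat", "cold", "extreme_heat", "extreme_cold")) {
    got <- attributable_fraction(cmmt, cs, mmt, component = cm)
    want <- edf_loop_oracle(curve, cs, mmt, cm)
    expect_lt(abs(got$attributable_deaths - want$attributable_deaths), 1e-12 *
                max(1, abs(want$attributable_deaths)))
    expect_lt(abs(got$edf_pct - want$edf_pct), 1e-12 * max(1, abs(want$edf_pct)))
  }
  # heat and cold partition the off-MMT days
  h <- attributable_fraction(cmmt, cs, mmt, "heat")
  c_ <- attributable_fraction(cmmt, cs, mmt, "cold")
  tot <- attributable_fraction(cmmt, cs, mmt, "total")
  expect_lt(abs(h$edf_pct + c_$edf_pct - tot$edf_pct), 1e-10)
})

test_that("EDF Monte Carlo intervals behave at the degenerate ends", {
  cs <- make_test_city(n_years = 1, seed = 31)
  sp <- exposure_spec_from_temps(cs$data$temp_c)
  co <- c(0.05, 0.1, 0.2, 0.15)
  tight <- reduced_curve(co, diag(1e-18, 4), sp, 20)
  mmt <- find_mmt(tight, cs$data$temp_c)
  ec <- edf_confidence(tight, cs, mmt, "total", n_draws = 300, seed = 5)
  expect_lt(ec$ci_high - ec$ci_low, 1e-5)
  expect_equal(ec$estimate, mean(ec$draws), tolerance = 1e-4)
  # fixed seed reproduces the interval exactly
  loose <- reduced_curve(co, diag(0.01, 4), sp, 20)
  a <- edf_confidence(loose, cs, mmt, "heat", n_draws = 300, seed = 9)
  b <- edf_confidence(loose, cs, mmt, "heat", n_draws = 300, seed = 9)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_error(edf_confidence(loose, cs, mmt, n_draws = 50, seed = 1), "100")
})

test_that("extreme slopes follow the stated tail formula", {
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  set.seed(41)
  obs <- runif(2000, 0, 30)
  co <- rnorm(4, 0, 0.2)
  curve <- reduced_curve(co, diag(1e-4, 4), sp, 15)
  # manual composition from predict_curve
  tq <- empirical_percentile(obs, c(95, 99))
  pr <- predict_curve(curve, tq)
  manual_heat <- exp((pr$logrr[2] - pr$logrr[1]) / (tq[2] - tq[1]))
  sl <- extreme_slope(curve, obs, "heat", n_draws = 200, seed = 3)
  expect_equal(sl$rr_per_c, manual_heat, tolerance = 1e-10)
  tq2 <- empirical_percentile(obs, c(5, 1))
  pr2 <- predict_curve(curve, tq2)
  manual_cold <- exp((pr2$logrr[2] - pr2$logrr[1]) / (tq2[1] - tq2[2]))
  sl2 <- extreme_slope(curve, obs, "cold", n_draws = 200, seed = 3)
  expect_equal(sl2$rr_per_c, manual_cold, tolerance = 1e-10)
  # flat curve: slope RR = 1 on both sides
  flat <- reduced_curve(rep(0, 4), diag(1e-12, 4), sp, 15)
  expect_equal(extreme_slope(flat, obs, "heat", 200, seed = 1)$rr_per_c, 1)
  expect_equal(extreme_slope(flat, obs, "cold", 200, seed = 1)$rr_per_c, 1)
  # degenerate gap rejected
  expect_error(extreme_slope(curve, rep(10, 50), "heat", 200, seed = 1),
               "degenerate")
})

test_that("the worked tail-slope arithmetic reproduces by hand", {
  # logRR(T99) = log 1.2, logRR(T95) = log 1.1, gap 2 C -> RR/C ~ 1.0445
  manual <- exp((log(1.2) - log(1.1)) / 2)
  expect_equal(round(manual, 4), 1.0445)
})

test_that("RR at a percentile is invariant to the original centering", {
  cs <- make_test_city(n_years = 1, seed = 43)
  sp <- exposure_spec_from_temps(cs$data$temp_c)
  co <- c(0.1, 0.05, 0.3, 0.2)
  c1 <- reduced_curve(co, diag(0.001, 4), sp,
                      empirical_percentile(cs$data$temp_c, 50))
  c2 <- reduced_curve(co, diag(0.001, 4), sp,
                      empirical_percentile(cs$data$temp_c, 10))
  mmt <- find_mmt(c1, cs$data$temp_c)
  r1 <- rr_at_percentile(recentre_curve(c1, mmt), cs$data$temp_c, 95)
  r2 <- rr_at_percentile(recentre_curve(c2, mmt), cs$data$temp_c, 95)
  expect_equal(r1$rr, r2$rr, tolerance = 1e-12)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-12)
  # at the MMT itself the RR is 1 with a degenerate interval
  mmt_pct <- 100 * mean(cs$data$temp_c <= mmt)
  rx <- rr_at_percentile(recentre_curve(c1, mmt), cs$data$temp_c,
                         mmt_pct)
  expect_lt(abs(rx$rr - 1), 0.02)   # discrete percentile grid
  # composition with predict_curve
  t95 <- empirical_percentile(cs$data$temp_c, 95)
  expect_equal(r1$rr, predict_curve(recentre_curve(c1, mmt), t95)$rr)
})

test_that("risk summaries satisfy the additivity and nesting invariants", {
  cs <- make_test_city(n_years = 2, seed = 47)
  fit <- fit_conditional_poisson(cs, make_test_crossbasis(cs$data$temp_c))
  rs <- risk_summary(reduce_fit(fit), cs, n_draws = 300, seed = 13)
  expect_lt(abs(rs$edf_heat + rs$edf_cold - rs$edf_total), 1e-10)
  expect_lte(rs$edf_extreme_heat, rs$edf_heat + 1e-10)
  expect_lte(rs$edf_extreme_cold, rs$edf_cold + 1e-10)
  expect_true(all(abs(c(rs$edf_total, rs$edf_heat, rs$edf_cold)) < 100))
  # pooled study EDF is death-weighted, not averaged
  cs2 <- make_test_city(n_years = 2, seed = 48, baseline_rate = 40)
  fit2 <- fit_conditional_poisson(cs2, make_test_crossbasis(cs2$data$temp_c))
  rs2 <- risk_summary(reduce_fit(fit2), cs2, n_draws = 300, seed = 14)
  both <- rbind(rs, rs2)
  pooled <- pool_edf(both)
  expect_equal(pooled$edf_total,
               100 * sum(both$attr_deaths_total) / sum(both$total_deaths),
               tolerance = 1e-12)
})
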