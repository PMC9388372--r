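# Shared fixtures: everything is generated in code at test time.

# A small simulated city with sensible defaults for fast fits.
make_test_city <- function(n_years = 2, baseline_rate = 15, seed = 42,
                           true_curve = NULL, ...) {
  sc <- city_scenario(n_years = n_years, baseline_rate = baseline_rate,
                      seed = seed, true_curve = true_curve, ...)
  simulate_city(sc)
}

# Default cross-basis for a city's temperatures.
make_test_crossbasis <- function(temps) {
  build_cross_basis(temps, crossbasis_spec(exposure_spec_from_temps(temps)))
}

# Independent truncated-power natural cubic spline basis (intercept + linear
# + one function per knot beyond the last two), the textbook construction:
# N1 = 1, N2 = x, N_{j+2} = d_j(x) - d_{K-1}(x),
# d_j(x) = [(x - k_j)^3_+ - (x - k_K)^3_+] / (k_K - k_j).
# Spans the natural cubic splines on knots k_1 < ... < k_K (linear beyond
# k_1 and k_K).
tp_natural_basis <- function(x, knots) {
  K <- length(knots)
  pos3 <- function(u) pmax(u, 0)^3
  d <- function(j) (pos3(x - knots[j]) - pos3(x - knots[K])) / (knots[K] - knots[j])
  out <- cbind(1, x)
  for (j in seq_len(K - 2L)) out <- cbind(out, d(j) - d(K - 1L))
  out
}

# Least-squares fitted values of y on the column span of B (plus intercept).
span_fit <- function(B, y) {
  X <- cbind(1, B)
  drop(X %*% qr.coef(qr(X), y))
}

# Synthetic reduced curves around a common mean for meta-regression tests:
# y_i = mu + b_i + e_i with b_i ~ N(0, tau^2 I) and e_i ~ N(0, S_i).
make_meta_curves <- function(m, mu = c(0.1, -0.05, 0.2, 0.15), tau = 0.05,
                             S_list = NULL, seed = 1) {
  set.seed(seed)
  k <- length(mu)
  sp <- spline_spec(c(0, 30), c(10, 20, 25))
  if (is.null(S_list))
    S_list <- replicate(m, diag(0.03^2, k), simplify = FALSE)
  lapply(seq_len(m), function(i) {
    y <- mu + stats::rnorm(k, 0, tau) +
      drop(tempmort:::rmvnorm_chol(1, rep(0, k), S_list[[i]]))
    reduced_curve(y, S_list[[i]], sp, 15)
  })
}
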