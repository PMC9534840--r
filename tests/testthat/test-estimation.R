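test_that("cost normalization uses the ego's own extremes and includes them", {
  costs <- normalize_costs(toy_network())
  expect_equal(costs$sigma, 4)
  expect_equal(costs$t_bar, 2 / 3)
  expect_equal(unname(costs$t_values[c("B", "C", "D", "E", "F")]),
               c(0, 5 / 9, 8 / 9, 8 / 9, 1))
  # extremes are attained by construction
  expect_equal(min(costs$t_values), 0)
  expect_equal(max(costs$t_values), 1)
  # degenerate and undersized networks are refused
  expect_error(normalize_costs(ego_network("X", "g", c(a = 3, b = 3, c = 3))),
               "degenerate")
  expect_error(normalize_costs(ego_network("X", "g", c(a = 3))), "at least 2")
})

test_that("solve_eta inverts the mean-cost equation", {
  expect_identical(solve_eta(0.5), 0)
  # against an independent bisection oracle
  for (tb in c(0.05, 0.31, 2 / 3, 0.8, 0.97))
    expect_equal(solve_eta(tb), oracle_solve_eta(tb), tolerance = 1e-7)
  expect_equal(solve_eta(2 / 3), 2.1491258, tolerance = 1e-6)
  # round trip across regimes
  for (eta in c(-20, -10, -1, -0.1, 0.1, 0.5, 2, 6, 10, 20))
    expect_equal(solve_eta(mean_normalized_cost(eta)), eta, tolerance = 1e-6)
  expect_error(solve_eta(0), "infinite")
  expect_error(solve_eta(1), "infinite")
})

test_that("maximum likelihood coincides with the moment condition", {
  # the density is a one-parameter exponential family in t, so the
  # likelihood is maximized exactly where the model mean matches t_bar;
  # check the grid-search maximizer against solve_eta
  set.seed(5)
  grid <- seq(-20, 20, by = 0.01)
  for (i in 1:5) {
    eta0 <- stats::runif(1, -8, 8)
    t <- sample_costs(50, eta0)
    ll <- vapply(grid, oracle_loglik, numeric(1), t = t)
    expect_equal(grid[which.max(ll)], solve_eta(mean(t)), tolerance = 0.011)
  }
})

test_that("Wald interval brackets the estimate and narrows as 1/sqrt(L)", {
  t <- unname(normalize_costs(toy_network())$t_values)
  eta_hat <- solve_eta(mean(t))
  ci <- eta_confint(t, eta_hat)
  expect_lt(ci[1], eta_hat)
  expect_gt(ci[2], eta_hat)
  expect_error(eta_confint(t, eta_hat, delta = 0.7), "delta")

  # deterministic 1/sqrt(L) narrowing: build samples at the model quantiles
  # of eta = 6 so t_bar is essentially E[t] for every L; the CLT rate holds
  # once L is moderate, while at L = 10 the curvature of the inverse map
  # inflates the eta-scale width beyond the linearized prediction
  widths <- vapply(c(10, 40, 160), function(L) {
    q <- sample_costs_quantiles(L, 6)
    f <- fit_costs(q)
    f$ci_high - f$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.1)
  expect_gte(widths[1] / widths[2], 2)
})

test_that("bootstrap interval roughly agrees with the Wald interval", {
  set.seed(8)
  t <- sample_costs(80, 3)
  eta_hat <- solve_eta(mean(t))
  wald <- eta_confint(t, eta_hat)
  boot <- eta_confint_boot(t, n_boot = 499)
  expect_lt(abs(wald[1] - boot[1]), 1.5)
  expect_lt(abs(wald[2] - boot[2]), 1.5)
})

test_that("fit_ego composes normalization, inversion and interval", {
  fit <- fit_ego(toy_network())
  expect_s3_class(fit, "continuum_fit")
  expect_equal(fit$eta_hat, 2.1491258, tolerance = 1e-6)
  expect_equal(fit$L, 5L)
  expect_equal(fit$sigma, 4)
  expect_false(fit$degenerate)
  expect_true(fit$ci_low <= fit$eta_hat && fit$eta_hat <= fit$ci_high)
  # below the partner threshold: refused
  expect_error(fit_ego(ego_network("X", "g", c(a = 4, b = 3, c = 2, d = 1))),
               "L = 4 < 5")
  # degenerate network: flagged, non-fatal, no fitted value
  dg <- fit_ego(ego_network("X", "g",
                            c(a = 2, b = 2, c = 2, d = 2, e = 2)))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$eta_hat))
  expect_true(is.na(dg$regime))
})

test_that("regime labels follow the sign of eta with a boundary band", {
  set.seed(3)
  up <- fit_costs(sample_costs(400, 8))
  expect_identical(up$regime, "normal")
  down <- fit_costs(sample_costs(400, -8))
  expect_identical(down$regime, "inverted")
  near0 <- fit_costs(sample_costs(30, 0.05))
  expect_true(near0$regime %in% c("boundary", "normal", "inverted"))
  if (near0$ci_low < 0 && near0$ci_high > 0)
    expect_identical(near0$regime, "boundary")
})

test_that("empirical cost cdf groups ties and ends at one", {
  steps <- empirical_cost_cdf(normalize_costs(toy_network()))
  expect_equal(steps$t, c(0, 5 / 9, 8 / 9, 1))
  expect_equal(steps$fraction, c(0.2, 0.4, 0.8, 1.0))
  expect_equal(steps$fraction[nrow(steps)], 1)
  # attained extremes each carry mass 1/L at the first step
  expect_equal(steps$fraction[1], 1 / 5)
})

test_that("the confidence band is the monotone envelope of chi over the interval", {
  fit <- fit_costs(sample_costs_quantiles(50, 6))
  band <- fit_band(fit, t_grid = c(0, 0.5, 1))
  expect_equal(band$lower[1], 0); expect_equal(band$upper[1], 0)
  expect_equal(band$lower[3], 1); expect_equal(band$upper[3], 1)
  expect_equal(band$lower[2], continuum_cdf(0.5, fit$ci_high))
  expect_equal(band$upper[2], continuum_cdf(0.5, fit$ci_low))
  expect_true(all(band$lower <= band$chi & band$chi <= band$upper))
  # zero-width interval collapses the band onto the fitted curve
  fit0 <- fit
  fit0$ci_low <- fit0$ci_high <- fit0$eta_hat
  band0 <- fit_band(fit0, t_grid = seq(0, 1, 0.1))
  expect_equal(band0$lower, band0$chi)
  expect_equal(band0$upper, band0$chi)
  # degenerate fit: empty band
  dg <- fit_ego(ego_network("X", "g", c(a = 2, b = 2, c = 2, d = 2, e = 2)))
  expect_identical(nrow(fit_band(dg)), 0L)
})

test_that("interval coverage is close to nominal in a seeded simulation", {
  set.seed(21)
  eta0 <- 4; L <- 50; reps <- 300
  hits <- 0L
  for (i in seq_len(reps)) {
    f <- fit_costs(sample_costs(L, eta0))
    if (f$ci_low <= eta0 && eta0 <= f$ci_high) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.90)
  expect_lt(hits / reps, 0.99)
})

test_that("direct-draw recovery is unbiased within Monte-Carlo error", {
  res <- recovery_experiment(data.frame(eta_true = 6, L = 500),
                             replicates = 100, mode = "direct", seed = 13)
  expect_identical(nrow(res), 1L)
  # CLT: se(eta_hat) = 1/sqrt(L * Var[t; 6]) ~ 0.28, so the mean of 100
  # replicates sits within ~3 * 0.028 of truth
  expect_lt(abs(res$bias), 0.1)
  expect_lt(res$rmse, 0.45)
  expect_gt(res$coverage, 0.89)
})
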