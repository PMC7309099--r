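# analytic reference models, closed forms, GDD transform, error metric

test_that("GDD transform clamps at the base temperature", {
  expect_equal(gdd_from_temperature(22.86), 12.86)
  expect_equal(gdd_from_temperature(18.40), 8.40)
  expect_equal(gdd_from_temperature(19.14), 9.14)
  expect_equal(gdd_from_temperature(10.0), 0)
  expect_equal(gdd_from_temperature(5), 0)
  expect_equal(gdd_from_temperature(25, base_c = 12), 13)
  expect_error(gdd_from_temperature(NaN), "non-finite")
})

test_that("cumulative GDD is the prefix sum", {
  expect_equal(cumulative_gdd(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(cumulative_gdd(numeric(0)), numeric(0))
  expect_equal(tail(cumulative_gdd(rep(12.86, 60)), 1), 771.6)
  expect_error(cumulative_gdd(c(1, -1)), "negative")
})

test_that("Boltzmann-sigmoid LAI hits its midpoint and asymptotes", {
  p <- carmassi_env1()
  expect_equal(carmassi_lai(560, p), (0.03 + 0.90) / 2)
  expect_equal(carmassi_lai(1e9, p), 0.90)
  expect_equal(carmassi_lai(0, p), 0.03 + 0.87 / (1 + exp(11.2)))
  # monotone increasing and bounded in (alpha, beta)
  g <- seq(0, 2000, by = 10)
  v <- carmassi_lai(g, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > p$alpha & v < p$beta))
  expect_error(carmassi_params(0.9, 0.3, 560, 50), "beta > alpha")
})

test_that("radiation-based ET model evaluates and saturates correctly", {
  p <- baille_env1()
  expect_equal(baille_et(0, 5, p), 0.32)
  expect_equal(baille_et(1e9, 12.82, p), 0.109 * 12.82 / 2.45 + 0.32)
  expect_equal(baille_et(1, 12.82, p),
               0.109 * (1 - exp(-0.69)) * 12.82 / 2.45 + 0.32,
               tolerance = 1e-12)
  expect_equal(round(baille_et(1, 12.82, p), 3), 0.604)
  # monotone in both arguments
  expect_true(all(diff(baille_et(seq(0, 5, 0.1), 10, p)) > 0))
  expect_true(all(diff(baille_et(2, seq(0, 20, 0.5), p)) > 0))
})

test_that("both closed forms satisfy dx/dt = -mu x + kappa mu exactly", {
  ts <- seq(0.5, 80, by = 0.5)
  kappa <- 1.4; mu <- 0.09; t0 <- 30
  x <- reciprocal_logistic_series(kappa, mu, t0, ts)
  dxdt <- -kappa * mu * exp(-mu * (ts - t0))  # analytic derivative
  expect_equal(dxdt, -mu * x + kappa * mu, tolerance = 1e-12)
  kp <- 2.2; mp <- 0.06
  xe <- et_closed_form(kp, mp, ts)
  dxe <- kp * mp * exp(-mp * ts)
  expect_equal(dxe, -mp * xe + kp * mp, tolerance = 1e-12)
  # the logistic curve is the reciprocal of the linear-dynamics solution
  expect_equal(logistic_series(kappa, mu, t0, ts), 1 / x)
  expect_true(all(diff(logistic_series(kappa, mu, t0, ts)) > 0))
  expect_true(all(diff(x) < 0))
  expect_equal(reciprocal_logistic_series(kappa, mu, t0, t0), 2 * kappa)
  expect_equal(et_closed_form(kp, mp, 0), 0)
})

test_that("Euler iteration converges to the closed form with O(Delta) error", {
  kappa <- 1; mu <- 0.1; x0 <- 5; horizon <- 10
  closed <- kappa + (x0 - kappa) * exp(-mu * horizon)
  err_at <- function(delta) {
    x <- x0
    for (i in seq_len(horizon / delta)) x <- difference_step(x, mu, kappa, delta)
    abs(x - closed)
  }
  e1 <- err_at(0.1); e2 <- err_at(0.05); e3 <- err_at(0.025)
  expect_lt(e2, e1); expect_lt(e3, e2)
  # halving Delta about halves the error (first-order convergence)
  expect_equal(e1 / e2, 2, tolerance = 0.2)
  expect_equal(e2 / e3, 2, tolerance = 0.2)
  # fixed point and mu = 0 degeneracies
  expect_equal(difference_step(kappa, mu, kappa, 1), kappa)
  expect_equal(difference_step(3.3, 0, kappa, 1), 3.3)
  expect_error(difference_step(1, 0.1, 1, 0), "delta")
})

test_that("linear benchmarks reproduce a normal-equations oracle", {
  # exactly collinear: zero residual, exact coefficients
  cg <- cumulative_gdd(rep(10, 6))
  y <- 0.5 + 0.02 * cg
  obs <- observation_series(1:6, y, rep(TRUE, 6))
  p <- fit_lrm_lai(obs, cg)
  expect_equal(p$rho0, 0.5, tolerance = 1e-10)
  expect_equal(p$rho1, 0.02, tolerance = 1e-10)
  expect_equal(p$resid_var, 0, tolerance = 1e-16)
  expect_equal(predict_lrm(p, cg), y)
  # two observed points: the line through them
  obs2 <- observation_series(1:6, c(1, NA, NA, 4, NA, NA),
                             c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  p2 <- fit_lrm_lai(obs2, cg)
  expect_equal(p2$rho0 + p2$rho1 * cg[1], 1, tolerance = 1e-10)
  expect_equal(p2$rho0 + p2$rho1 * cg[4], 4, tolerance = 1e-10)
  # ET model vs hand-rolled normal equations
  set.seed(14)
  n <- 12
  cg <- cumulative_gdd(stats::runif(n, 5, 15))
  R <- stats::runif(n, 2, 20)
  yet <- 0.3 + 0.002 * cg + 0.04 * R + stats::rnorm(n, 0, 0.05)
  obs3 <- observation_series(1:n, yet, rep(TRUE, n))
  p3 <- fit_lrm_et(obs3, cg, R)
  X <- cbind(1, cg, R)
  beta <- solve(crossprod(X), crossprod(X, yet))
  expect_equal(c(p3$rho0, p3$rho1, p3$rho2), drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_lrm_et(obs3, cg, rep(1, n) * 0 + cg), "rank-deficient")
  expect_error(fit_lrm_lai(observation_series(1:2, c(1, NA),
                                              c(TRUE, FALSE)), c(1, 2)),
               ">= 2 observed")
})

test_that("benchmark recalibration recovers generating constants", {
  set.seed(33)
  cg <- cumulative_gdd(stats::runif(80, 8, 16))
  lai <- carmassi_lai(cg, carmassi_params(0.05, 1.1, 500, 60))
  obs <- observation_series(1:80, lai, rep(TRUE, 80))
  p <- suppressWarnings(
    recalibrate_benchmark(obs, cum_gdd = cg, model = "carmassi"))
  expect_equal(p$zeta, 500, tolerance = 1)
  expect_equal(p$beta, 1.1, tolerance = 0.01)
  R <- stats::runif(80, 2, 20)
  et <- baille_et(lai, R, baille_params(0.12, 0.4))
  obs_et <- observation_series(1:80, et, rep(TRUE, 80))
  pb <- recalibrate_benchmark(obs_et, lai = lai, R = R, model = "baille")
  expect_equal(pb$epsilon_b, 0.12, tolerance = 1e-8)
  expect_equal(pb$gamma, 0.4, tolerance = 1e-8)
})

test_that("prediction error metric is a mean absolute percentage", {
  expect_equal(prediction_error_pct(c(1, 2), c(1, 2)), 0)
  expect_equal(prediction_error_pct(c(1.1, 1.8), c(1, 2)), 10)
  expect_equal(prediction_error_pct(3, 2), 50)
  # scale invariance
  set.seed(2)
  p <- stats::runif(10, 1, 3); o <- stats::runif(10, 1, 3)
  expect_equal(prediction_error_pct(p, o),
               prediction_error_pct(10 * p, 10 * o))
  expect_warning(prediction_error_pct(c(1, 1), c(0, 2)), "zero observation")
  expect_error(prediction_error_pct(1, c(1, 2)), "length mismatch")
  # relative-RMSE alternative
  expect_equal(prediction_error_pct(c(1.1, 1.9), c(1, 2), method = "rrmse"),
               100 * sqrt(mean(c(0.1, 0.1)^2)) / 1.5)
})
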