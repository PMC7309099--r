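# EM learning: sufficient statistics, closed-form M-step, monotone fits

test_that("noise-free fully observed states give exact second moments", {
  ctl <- control_series(1:10, matrix(10, 10, 1))
  # zero state/initial noise: the state path is deterministic and the
  # posterior state variance collapses to V_t = 0 exactly
  th <- dbn_params(A = 0.02, B = 0.02, C = 1, Sigma_n = 0, Sigma_w = 1e-12,
                   mu_1 = 5, Sigma_1 = 0)
  obs <- simulate_trajectory(th, ctl, seed = 1)$obs
  es <- e_step(th, ctl, obs)
  expect_equal(drop(es$stats$Exx[1, 1, ]), drop(es$stats$Ex)^2,
               tolerance = 1e-12)
})

test_that("e_step statistics match the joint-Gaussian posterior at T=3", {
  set.seed(8)
  th <- dbn_params(A = 0.05, B = 0.04, C = 1.1, Sigma_n = 0.04, Sigma_w = 0.09,
                   mu_1 = 2.5, Sigma_1 = 0.3)
  ctl <- control_series(1:3, matrix(c(9, 12, 10), 3, 1))
  obs <- observation_series(1:3, c(2.8, NA, 2.2), c(TRUE, FALSE, TRUE))
  es <- e_step(th, ctl, obs)
  op <- oracle_posterior(th, ctl, obs)
  for (t in 1:3) {
    Exx_ref <- oracle_block(op, t, t) + tcrossprod(op$mean[t, ])
    expect_equal(drop(es$stats$Exx[, , t]), drop(Exx_ref), tolerance = 1e-8)
    if (t > 1) {
      Exx1_ref <- oracle_block(op, t, t - 1) +
        tcrossprod(op$mean[t, ], op$mean[t - 1, ])
      expect_equal(drop(es$stats$Exx1[, , t]), drop(Exx1_ref),
                   tolerance = 1e-8)
    }
  }
  expect_equal(drop(es$stats$Ex), drop(op$mean), tolerance = 1e-8)
})

test_that("all-missing series yields prior moments as statistics", {
  th <- dbn_params(A = 0.02, B = 0.02, C = 1, Sigma_n = 0.01, Sigma_w = 0.1,
                   mu_1 = 3, Sigma_1 = 0.2)
  ctl <- control_series(1:4, matrix(8, 4, 1))
  obs <- observation_series(1:4, rep(NA_real_, 4), rep(FALSE, 4))
  es <- e_step(th, ctl, obs)
  jm <- joint_state_moments(th, ctl)
  expect_equal(drop(es$stats$Ex), jm$mu, tolerance = 1e-10)
  expect_equal(es$stats$n_obs, 0L)
})

test_that("m_step recovers generating (A, B) exactly from noise-free data", {
  ctl <- control_series(1:12, matrix(seq(8, 14, length.out = 12), 12, 1))
  A_true <- 0.015; B_true <- 0.011
  th <- dbn_params(A = A_true, B = B_true, C = 1, Sigma_n = 0,
                   Sigma_w = 1e-12, mu_1 = 6, Sigma_1 = 0)
  obs <- simulate_trajectory(th, ctl, seed = 2)$obs
  # zero state noise: the posterior is the exact deterministic state path
  es <- e_step(th, ctl, obs)
  up <- m_step(es$stats, ctl, obs, prev = th)
  expect_equal(up$A[1, 1], A_true, tolerance = 1e-10)
  expect_equal(up$B[1, 1], B_true, tolerance = 1e-10)
})

test_that("m_step (A, B) equals a direct normal-equations least-squares oracle", {
  set.seed(31)
  th <- dbn_params(A = 0.03, B = 0.02, C = 1, Sigma_n = 0.02, Sigma_w = 0.05,
                   mu_1 = 3, Sigma_1 = 0.1)
  ctl <- control_series(1:4, matrix(c(7, 9, 12, 10), 4, 1))
  obs <- simulate_trajectory(th, ctl, seed = 3)$obs
  es <- e_step(th, ctl, obs)
  up <- m_step(es$stats, ctl, obs, prev = th)
  # independent oracle: minimize sum_t E[(d_t + a u_t x_t - b u_t)^2] by
  # solving the 2x2 normal equations assembled directly from the moments
  S <- es$stats
  u <- drop(ctl$u)
  M <- matrix(0, 2, 2); v <- numeric(2)
  for (t in 1:3) {
    Exx <- S$Exx[1, 1, t]; Ex <- S$Ex[1, t]; Ex1 <- S$Ex[1, t + 1]
    Exx1 <- S$Exx1[1, 1, t + 1]
    M <- M + matrix(c(u[t]^2 * Exx, -u[t]^2 * Ex,
                      -u[t]^2 * Ex, u[t]^2), 2, 2)
    v <- v + c(-u[t] * (Exx1 - Exx), u[t] * (Ex1 - Ex))
  }
  ab <- solve(M, v)
  expect_equal(up$A[1, 1], ab[1], tolerance = 1e-10)
  expect_equal(up$B[1, 1], ab[2], tolerance = 1e-10)
})

test_that("frozen parameters pass through the M-step bit-identically", {
  set.seed(12)
  sc <- random_scenario(2, 6, p_obs = 0.8, min_obs = 2)
  es <- e_step(sc$params, sc$controls, sc$obs)
  up <- m_step(es$stats, sc$controls, sc$obs,
               freeze = c("C", "Sigma_w"), prev = sc$params)
  expect_identical(up$C, sc$params$C)
  expect_identical(up$Sigma_w, sc$params$Sigma_w)
  expect_false(identical(up$A, sc$params$A))
  # freezing everything returns the input parameters
  all_names <- c("A", "B", "C", "Sigma_n", "Sigma_w", "mu_1", "Sigma_1")
  up2 <- m_step(es$stats, sc$controls, sc$obs, freeze = all_names,
                prev = sc$params)
  expect_equal(up2$A, sc$params$A)
  expect_equal(up2$Sigma_1, sc$params$Sigma_1)
  expect_error(m_step(es$stats, sc$controls, sc$obs, freeze = "Q",
                      prev = sc$params),
               "unknown parameter")
})

test_that("m_step is the exact argmax of the expected complete-data loglik", {
  set.seed(77)
  sc <- random_scenario(1, 8, p_obs = 0.8, min_obs = 2)
  es <- e_step(sc$params, sc$controls, sc$obs)
  up <- m_step(es$stats, sc$controls, sc$obs, prev = sc$params)
  q0 <- cropdbn:::q_fn(up, es$stats, sc$controls, sc$obs)
  perturb <- function(th, field, h) {
    th[[field]] <- th[[field]] + h
    dbn_params(th$A, th$B, th$C, th$Sigma_n, th$Sigma_w, th$mu_1, th$Sigma_1)
  }
  for (field in c("A", "B", "C", "Sigma_n", "Sigma_w", "mu_1")) {
    for (h in c(-1e-3, 1e-3)) {
      thp <- tryCatch(perturb(up, field, h), error = function(e) NULL)
      if (is.null(thp)) next  # perturbation left the PSD cone
      qp <- cropdbn:::q_fn(thp, es$stats, sc$controls, sc$obs)
      expect_lte(qp, q0 + 1e-10)
    }
  }
})

test_that("EM restarted at a stationary point converges immediately", {
  ctl <- control_series(1:10, matrix(seq(9, 12, length.out = 10), 10, 1))
  th <- dbn_params(A = 0.02, B = 0.02, C = 1, Sigma_n = 1e-4, Sigma_w = 1e-3,
                   mu_1 = 5, Sigma_1 = 1e-3)
  obs <- simulate_trajectory(th, ctl, seed = 44)$obs
  fit1 <- fit_em(th, ctl, obs, max_iter = 100)
  # restarting from the converged parameters changes nothing
  fit2 <- fit_em(fit1$theta_final, ctl, obs, max_iter = 10)
  expect_lte(fit2$n_iter, 2)
  expect_true(fit2$converged)
})

test_that("EM recovers the generating dynamics from partial observations", {
  set.seed(2024)
  prof <- env_profile("env1", n_days = 200)
  env <- generate_environment(prof)
  ctl <- control_series(1:200, cbind(gdd_from_temperature(env$temp_c)))
  A_true <- 0.11 / mean(ctl$u)
  th <- dbn_params(A = A_true, B = A_true, C = 1, Sigma_n = 1e-4,
                   Sigma_w = 1e-2, mu_1 = 33, Sigma_1 = 1e-4)
  sim <- simulate_trajectory(th, ctl)
  obs <- apply_mar_mask(sim$obs, 0.70, keep_first = 2)
  th0 <- build_initial_theta(obs, ctl, mode = "reciprocal_lai")
  fit <- fit_em(th0, ctl, obs, freeze = "C")
  expect_lt(abs(fit$theta_final$A[1, 1] - A_true) / A_true, 0.15)
  expect_lt(abs(fit$theta_final$B[1, 1] - A_true) / A_true, 0.15)
})

test_that("the log-likelihood trace is non-decreasing over random fits", {
  set.seed(404)
  for (i in 1:25) {
    sc <- random_scenario(sample(1:2, 1), 15, p_obs = stats::runif(1, 0.4, 1),
                          min_obs = 2)
    th0 <- random_params(sc$params$K)
    fit <- tryCatch(fit_em(th0, sc$controls, sc$obs, max_iter = 40),
                    error = function(e) e)
    # fit_em itself errors on any decrease beyond 1e-8; reaching here with a
    # trace is the assertion, plus an explicit check on the returned trace
    expect_false(inherits(fit, "error"))
    expect_true(all(diff(fit$loglik_per_iter) >=
                      -1e-8 * pmax(1, abs(fit$loglik_per_iter[-1]))))
  }
})

test_that("recovery improves with longer series and denser observation", {
  set.seed(555)
  err_for <- function(TT, p_obs) {
    errs <- sapply(1:5, function(s) {
      prof <- env_profile("env1", n_days = TT)
      env <- generate_environment(prof)
      ctl <- control_series(1:TT, cbind(gdd_from_temperature(env$temp_c)))
      A_true <- 0.11 / mean(ctl$u)
      th <- dbn_params(A = A_true, B = A_true, C = 1, Sigma_n = 1e-4,
                       Sigma_w = 1e-2, mu_1 = 33, Sigma_1 = 1e-4)
      sim <- simulate_trajectory(th, ctl)
      obs <- apply_mar_mask(sim$obs, 1 - p_obs, keep_first = 2)
      th0 <- build_initial_theta(obs, ctl, mode = "reciprocal_lai")
      fit <- fit_em(th0, ctl, obs, freeze = "C")
      abs(fit$theta_final$A[1, 1] - A_true) / A_true
    })
    median(errs)
  }
  sparse_short <- err_for(100, 0.1)
  dense_long <- err_for(400, 1.0)
  expect_lt(dense_long, sparse_short)
})

test_that("degenerate inputs are refused with clear errors", {
  ctl <- control_series(1:5, matrix(10, 5, 1))
  obs <- observation_series(1:5, rep(NA_real_, 5), rep(FALSE, 5))
  th <- random_params(1)
  expect_error(fit_em(th, ctl, obs), "at least 2 observed")
  obs1 <- observation_series(1:5, c(3, NA, NA, NA, NA),
                             c(TRUE, rep(FALSE, 4)))
  expect_error(fit_em(th, ctl, obs1), "at least 2 observed")
})
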