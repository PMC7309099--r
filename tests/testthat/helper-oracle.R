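# Brute-force joint-Gaussian oracle, fully independent of the package's
# filter/smoother: builds the exact joint normal distribution of the stacked
# state vector (x_1, ..., x_T) and the observed measurements by unrolling the
# linear recursion, then conditions on the observed y by direct linear
# algebra. Tractable for the tiny T and K the tests use.

# joint moments of x (stacked KT vector) under the model
joint_state_moments <- function(params, controls) {
  K <- params$K
  TT <- length(controls$times)
  mu <- numeric(K * TT)
  S <- matrix(0, K * TT, K * TT)
  idx <- function(t) ((t - 1) * K + 1):(t * K)
  mu[idx(1)] <- params$mu_1
  S[idx(1), idx(1)] <- params$Sigma_1
  if (TT > 1) for (t in 1:(TT - 1)) {
    Ft <- diag(K) - params$A %*% diag(controls$u[t, ], K)
    mu[idx(t + 1)] <- Ft %*% mu[idx(t)] + params$B %*% controls$u[t, ]
    for (s in 1:t) {
      blk <- Ft %*% S[idx(t), idx(s)]
      S[idx(t + 1), idx(s)] <- blk
      S[idx(s), idx(t + 1)] <- t(blk)
    }
    S[idx(t + 1), idx(t + 1)] <-
      Ft %*% S[idx(t), idx(t)] %*% t(Ft) + params$Sigma_n
  }
  list(mu = mu, S = S, idx = idx)
}

# exact posterior of all states given observed y, plus log marginal density
oracle_posterior <- function(params, controls, obs) {
  jm <- joint_state_moments(params, controls)
  K <- params$K
  TT <- length(obs$times)
  oi <- which(obs$observed)
  n <- length(oi)
  if (n == 0) {
    return(list(mean = matrix(jm$mu, TT, K, byrow = TRUE),
                cov = jm$S, loglik = 0, idx = jm$idx))
  }
  # H maps stacked x to the observed y vector
  H <- matrix(0, n, K * TT)
  for (j in seq_len(n)) H[j, jm$idx(oi[j])] <- params$C
  Syy <- H %*% jm$S %*% t(H) + diag(params$Sigma_w[1, 1], n)
  Sxy <- jm$S %*% t(H)
  yv <- obs$y[oi]
  r <- yv - drop(H %*% jm$mu)
  Syy_inv_r <- solve(Syy, r)
  post_mu <- jm$mu + drop(Sxy %*% Syy_inv_r)
  post_S <- jm$S - Sxy %*% solve(Syy, t(Sxy))
  ld <- determinant(Syy, logarithm = TRUE)$modulus
  loglik <- -0.5 * (n * log(2 * pi) + as.numeric(ld) + sum(r * Syy_inv_r))
  list(mean = matrix(post_mu, TT, K, byrow = TRUE), cov = post_S,
       loglik = loglik, idx = jm$idx)
}

# marginal K x K block Cov(x_t, x_s | y_obs) from the oracle posterior
oracle_block <- function(op, t, s) op$cov[op$idx(t), op$idx(s), drop = FALSE]

# random valid parameters for property sweeps (stable-ish dynamics)
random_params <- function(K) {
  A <- diag(stats::runif(K, 0.005, 0.05), K)
  if (K > 1) A[upper.tri(A)] <- stats::runif(K * (K - 1) / 2, -0.01, 0.01)
  B <- A * stats::runif(1, 0.5, 2)
  Ln <- matrix(stats::rnorm(K * K, 0, 0.05), K)
  dbn_params(A = A, B = B, C = stats::runif(K, 0.5, 1.5),
             Sigma_n = Ln %*% t(Ln) + diag(1e-4, K),
             Sigma_w = stats::runif(1, 0.01, 0.2),
             mu_1 = stats::runif(K, 1, 5),
             Sigma_1 = diag(stats::runif(K, 0.01, 0.3), K))
}

random_scenario <- function(K, TT, p_obs = 0.6, min_obs = 0) {
  params <- random_params(K)
  ctl <- control_series(seq_len(TT),
                        matrix(stats::runif(TT * K, 2, 15), TT, K))
  sim <- simulate_trajectory(params, ctl)
  observed <- stats::runif(TT) < p_obs
  if (sum(observed) < min_obs)
    observed[sample.int(TT, min_obs)] <- TRUE
  obs <- observation_series(seq_len(TT),
                            ifelse(observed, sim$obs$y, NA_real_), observed)
  list(params = params, controls = ctl, obs = obs)
}

# tolerance helper: absolute-or-relative agreement
agree <- function(a, b, tol) {
  all(abs(a - b) <= tol * pmax(1, abs(b)))
}
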