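#' Conditional mean of the state transition
#'
#' Computes \eqn{(I - A\,\mathrm{diag}(u_t))\,x_t + B u_t}, the mean of the
#' next hidden state given the current one. With a diagonal `A` proportional
#' to the logistic decay and `B = A \kappa`, iterating this map reproduces the
#' Euler discretization of the reciprocal-logistic growth curve.
#'
#' @param x_t numeric state vector of length K.
#' @param u_t numeric control vector of length K.
#' @param params a [dbn_params()] object.
#' @return Numeric vector of length K.
#' @examples
#' th <- dbn_params(A = 0.1, B = 0.1, C = 1, Sigma_n = 0, Sigma_w = 0,
#'                  mu_1 = 2, Sigma_1 = 0)
#' transition_mean(2, 1, th)  # 0.9 * 2 + 0.1 = 1.9
#' @export
transition_mean <- function(x_t, u_t, params) {
  x_t <- as.numeric(x_t); u_t <- as.numeric(u_t)
  if (length(x_t) != params$K)
    stop("transition_mean: state 'x_t' has length ", length(x_t),
         " but K = ", params$K)
  if (length(u_t) != params$K)
    stop("transition_mean: control 'u_t' has length ", length(u_t),
         " but K = ", params$K)
  drop((diag(params$K) - params$A %*% diag(u_t, params$K)) %*% x_t +
         params$B %*% u_t)
}

#' Conditional mean of the emission
#'
#' Computes \eqn{C x_t}, the noiseless measurement for a given hidden state.
#'
#' @inheritParams transition_mean
#' @return A scalar.
#' @export
emission_mean <- function(x_t, params) {
  x_t <- as.numeric(x_t)
  if (length(x_t) != params$K)
    stop("emission_mean: state 'x_t' has length ", length(x_t),
         " but measurement matrix C has ", params$K, " columns")
  drop(params$C %*% x_t)
}

# internal: sample N(mean, Sigma) allowing singular / zero Sigma
rmvn1 <- function(mean, Sigma) {
  K <- length(mean)
  Sigma <- symm(Sigma)
  if (max(abs(Sigma)) == 0) return(mean)
  ee <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  mean + drop(ee$vectors %*% (sqrt(ev) * stats::rnorm(K)))
}

#' Simulate a trajectory from the generative model
#'
#' Draws a hidden state sequence and fully observed measurements from the
#' model: \eqn{x_1 \sim N(\mu_1, \Sigma_1)}, then
#' \eqn{x_{t+1} \sim N((I - A U_t) x_t + B u_t, \Sigma_n)} and
#' \eqn{y_t \sim N(C x_t, \Sigma_w)}.
#'
#' @param params a [dbn_params()] object.
#' @param controls a [control_series()].
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return A list with `states` (list: `times`, `x` T x K matrix) and
#'   `obs` (an [observation_series()], fully observed).
#' @examples
#' ctl <- control_series(1:20, matrix(12.86, 20, 1))
#' th <- dbn_params(A = 0.11 / 12.86, B = 0.11 / 12.86, C = 1,
#'                  Sigma_n = 1e-4, Sigma_w = 1e-2, mu_1 = 30, Sigma_1 = 0)
#' sim <- simulate_trajectory(th, ctl, seed = 1)
#' head(sim$obs$y)
#' @export
simulate_trajectory <- function(params, controls, seed = NULL) {
  stopifnot(inherits(params, "dbn_params"))
  check_dims(params, controls)
  if (!is.null(seed)) set.seed(seed)
  TT <- length(controls$times)
  K <- params$K
  x <- matrix(NA_real_, TT, K)
  y <- numeric(TT)
  x[1, ] <- rmvn1(params$mu_1, params$Sigma_1)
  sw <- sqrt(params$Sigma_w[1, 1])
  y[1] <- emission_mean(x[1, ], params) +
    (if (sw > 0) stats::rnorm(1, 0, sw) else 0)
  if (TT > 1) for (t in 1:(TT - 1)) {
    m <- transition_mean(x[t, ], controls$u[t, ], params)
    x[t + 1, ] <- rmvn1(m, params$Sigma_n)
    y[t + 1] <- emission_mean(x[t + 1, ], params) +
      (if (sw > 0) stats::rnorm(1, 0, sw) else 0)
  }
  list(states = list(times = controls$times, x = x),
       obs = observation_series(controls$times, y, rep(TRUE, TT)))
}
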