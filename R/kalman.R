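# Exact inference for the control-driven linear-Gaussian model.
#
# Missing measurements are handled by marginalization: on unobserved days the
# filter only runs its prediction step, so the likelihood of the observed data
# is accumulated over observed days alone. No imputation anywhere.

# floor for the scalar innovation variance; keeps the log-likelihood finite
# when Sigma_w is initialized very small
.INNOV_FLOOR <- 1e-12

#' Kalman filter with missing observations marginalized out
#'
#' Runs the forward pass of exact inference for the model in [dbn_params()].
#' Every day gets a prediction step through the time-varying transition
#' \eqn{I - A\,\mathrm{diag}(u_{t-1})}; the correction step is applied only on
#' observed days. The log-likelihood accumulates the Gaussian innovation
#' density over observed days only, which is the marginal likelihood
#' \eqn{\ln p(y^{(obs)} \mid \theta)} of the observed data.
#'
#' Covariance corrections use the Joseph form for numerical stability, and
#' each covariance is symmetrized after updating.
#'
#' @param params a [dbn_params()] object.
#' @param controls a [control_series()] aligned with `obs`.
#' @param obs an [observation_series()].
#' @return A list with `mean` (T x K filtered means), `cov` (K x K x T),
#'   `pred_mean`, `pred_cov` (one-step-ahead prior moments per day) and
#'   `loglik`.
#' @seealso [kalman_smooth()], [loglikelihood()]
#' @export
kalman_filter <- function(params, controls, obs) {
  stopifnot(inherits(params, "dbn_params"))
  check_aligned(controls, obs)
  check_dims(params, controls)
  TT <- length(obs$times)
  K <- params$K
  m_f <- matrix(NA_real_, TT, K)
  P_f <- array(NA_real_, c(K, K, TT))
  m_p <- matrix(NA_real_, TT, K)
  P_p <- array(NA_real_, c(K, K, TT))
  C <- params$C
  sw <- params$Sigma_w[1, 1]
  IK <- diag(K)
  ll <- 0
  m_prior <- params$mu_1
  P_prior <- params$Sigma_1
  for (t in seq_len(TT)) {
    if (t > 1) {
      Ft <- IK - params$A %*% diag(controls$u[t - 1, ], K)
      m_prior <- drop(Ft %*% m_f[t - 1, ] + params$B %*% controls$u[t - 1, ])
      P_prior <- symm(Ft %*% P_f[, , t - 1] %*% t(Ft) + params$Sigma_n)
    }
    m_p[t, ] <- m_prior
    P_p[, , t] <- P_prior
    if (obs$observed[t]) {
      S <- drop(C %*% P_prior %*% t(C)) + sw
      if (S <= 0)
        stop("kalman_filter: singular innovation variance at day ",
             obs$times[t], " (Sigma_w = 0 and C V C' = 0)")
      S <- max(S, .INNOV_FLOOR)
      innov <- obs$y[t] - drop(C %*% m_prior)
      Kg <- (P_prior %*% t(C)) / S
      m_f[t, ] <- m_prior + drop(Kg) * innov
      ImKC <- IK - Kg %*% C
      P_f[, , t] <- symm(ImKC %*% P_prior %*% t(ImKC) + (Kg %*% t(Kg)) * sw)
      ll <- ll - 0.5 * (log(2 * pi) + log(S) + innov^2 / S)
    } else {
      m_f[t, ] <- m_prior
      P_f[, , t] <- P_prior
    }
  }
  list(mean = m_f, cov = P_f, pred_mean = m_p, pred_cov = P_p, loglik = ll)
}

#' Rauch-Tung-Striebel smoothing with lag-one covariances
#'
#' Backward pass over the filtered moments, producing the posterior of each
#' day's hidden state given *all* observed measurements,
#' \eqn{E\{x_t \mid y^{(obs)}, \theta\}} and
#' \eqn{\mathrm{Cov}\{x_t \mid y^{(obs)}, \theta\}}, plus the lag-one
#' cross-covariances \eqn{\mathrm{Cov}\{x_t, x_{t-1} \mid y^{(obs)}\}}
#' needed by the EM sufficient statistics (via the identity
#' \eqn{\mathrm{Cov}(x_{t+1}, x_t \mid y) = \hat V_{t+1} J_t^\top}).
#'
#' @inheritParams kalman_filter
#' @return An object of class `"smoothed_posterior"`: list with `mean`
#'   (T x K), `cov` (K x K x T), `lag1_cov` (K x K x T; slice `t` holds
#'   \eqn{\mathrm{Cov}(x_t, x_{t-1})}, slice 1 is `NA`), `loglik`, `times`.
#' @export
kalman_smooth <- function(params, controls, obs) {
  kf <- kalman_filter(params, controls, obs)
  TT <- length(obs$times)
  K <- params$K
  m_s <- kf$mean
  P_s <- kf$cov
  L1 <- array(NA_real_, c(K, K, TT))
  IK <- diag(K)
  if (TT > 1) {
    for (t in (TT - 1):1) {
      Ft <- IK - params$A %*% diag(controls$u[t, ], K)
      Ppred <- kf$pred_cov[, , t + 1]
      # J_t = P^f_t F_t' inv(P^pred_{t+1}); use a pseudo-inverse-style solve
      # so degenerate (zero-noise) models smooth cleanly
      J <- t(solve_psd(Ppred, Ft %*% kf$cov[, , t]))
      m_s[t, ] <- kf$mean[t, ] +
        drop(J %*% (m_s[t + 1, ] - kf$pred_mean[t + 1, ]))
      P_s[, , t] <- symm(kf$cov[, , t] +
                           J %*% (P_s[, , t + 1] - Ppred) %*% t(J))
      L1[, , t + 1] <- P_s[, , t + 1] %*% t(J)
    }
  }
  structure(list(mean = m_s, cov = P_s, lag1_cov = L1, loglik = kf$loglik,
                 times = obs$times),
            class = "smoothed_posterior")
}

# internal: solve M %*% X = Bmat for symmetric PSD M, falling back to an
# eigenvalue pseudo-inverse when M is (numerically) singular
solve_psd <- function(M, Bmat) {
  M <- symm(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(backsolve(ch, forwardsolve(t(ch), Bmat)))
  ee <- eigen(M, symmetric = TRUE)
  tol <- max(abs(ee$values)) * 1e-12 + 1e-300
  inv_ev <- ifelse(ee$values > tol, 1 / ee$values, 0)
  ee$vectors %*% (inv_ev * (t(ee$vectors) %*% Bmat))
}

#' Marginal log-likelihood of the observed measurements
#'
#' \eqn{\ln p(y^{(obs)} \mid \theta)}, the filter's accumulated innovation
#' log-density over observed days. A series with no observed day has
#' log-likelihood 0 (the empty product).
#'
#' @inheritParams kalman_filter
#' @return A scalar.
#' @export
loglikelihood <- function(params, controls, obs) {
  kalman_filter(params, controls, obs)$loglik
}
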