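# Exact EM for the control-driven linear-Gaussian growth model.
#
# E-step: smoothed posterior moments (means, covariances, lag-one
# covariances) under the current parameters. M-step: closed-form maximizers
# of the expected complete-data log-likelihood. The transition residual
# x_{t+1} - x_t + A (u_t * x_t) - B u_t is linear in the stacked matrix
# [A | B], so (A, B) are maximized jointly by one multivariate least-squares
# solve on expected moments.

#' E-step: expected sufficient statistics
#'
#' Runs the smoother under the current parameters and assembles the expected
#' first and second moments of the hidden states that the M-step needs:
#' \eqn{E[x_t]}, \eqn{E[x_t x_t^\top] = V_t + \hat x_t \hat x_t^\top},
#' \eqn{E[x_t x_{t-1}^\top]}, and the observed-day cross moments with
#' \eqn{y_t}.
#'
#' @inheritParams kalman_filter
#' @return A list with `stats` (class `"dbn_suffstats"`) and `loglik`.
#' @export
e_step <- function(params, controls, obs) {
  sp <- kalman_smooth(params, controls, obs)
  TT <- length(obs$times)
  K <- params$K
  Ex <- t(sp$mean)                       # K x T
  Exx <- array(NA_real_, c(K, K, TT))
  Exx1 <- array(NA_real_, c(K, K, TT))   # slice t: E[x_t x_{t-1}']
  for (t in seq_len(TT)) {
    Exx[, , t] <- symm(sp$cov[, , t] + tcrossprod(Ex[, t]))
    if (t > 1)
      Exx1[, , t] <- sp$lag1_cov[, , t] + tcrossprod(Ex[, t], Ex[, t - 1])
  }
  oi <- which(obs$observed)
  S_yx <- matrix(0, 1, K)
  S_xx_obs <- matrix(0, K, K)
  S_yy <- 0
  for (t in oi) {
    S_yx <- S_yx + obs$y[t] * t(Ex[, t, drop = FALSE])
    S_xx_obs <- S_xx_obs + Exx[, , t]
    S_yy <- S_yy + obs$y[t]^2
  }
  stats <- structure(list(Ex = Ex, Exx = Exx, Exx1 = Exx1,
                          S_yx = S_yx, S_xx_obs = symm(S_xx_obs),
                          S_yy = S_yy, n_obs = length(oi), T = TT, K = K),
                     class = "dbn_suffstats")
  list(stats = stats, loglik = sp$loglik)
}

#' M-step: closed-form parameter maximizers
#'
#' Maximizes the expected complete-data log-likelihood given the E-step
#' statistics. `A` and `B` are solved jointly: writing the transition
#' residual as \eqn{d_t + [A\;B] z_t} with \eqn{d_t = x_{t+1} - x_t} and
#' \eqn{z_t = (u_t \odot x_t, -u_t)}, the maximizer is
#' \eqn{[A\;B] = -S_{dz} S_{zz}^{-1}} on expected moments. `C` and
#' \eqn{\Sigma_w} use observed days only; \eqn{\mu_1, \Sigma_1} come from the
#' smoothed initial state; \eqn{\Sigma_n} from expected transition residual
#' outer products. All covariance updates are symmetrized.
#'
#' @param stats a `"dbn_suffstats"` object from [e_step()].
#' @param controls the [control_series()] the statistics were computed under.
#' @param obs the matching [observation_series()].
#' @param freeze character vector of parameter names among
#'   `"A", "B", "C", "Sigma_n", "Sigma_w", "mu_1", "Sigma_1"` to pass through
#'   unchanged from `prev`.
#' @param prev the current [dbn_params()]; required whenever `freeze` is
#'   non-empty and used for dimensions otherwise.
#' @return A new [dbn_params()] object.
#' @export
m_step <- function(stats, controls, obs, freeze = character(), prev = NULL) {
  stopifnot(inherits(stats, "dbn_suffstats"))
  if (length(freeze) > 0 && is.null(prev))
    stop("m_step: 'prev' parameters are required when freezing")
  bad <- setdiff(freeze, c("A", "B", "C", "Sigma_n", "Sigma_w",
                           "mu_1", "Sigma_1"))
  if (length(bad) > 0)
    stop("m_step: unknown parameter name(s) in 'freeze': ",
         paste(bad, collapse = ", "))
  K <- stats$K
  TT <- stats$T
  u <- controls$u

  # -- (A, B) ---------------------------------------------------------------
  # per-day expected moments of z_t = (u_t*x_t, -u_t) and d_t = x_{t+1} - x_t
  Szz <- matrix(0, 2 * K, 2 * K)
  Sdz <- matrix(0, K, 2 * K)
  ia <- 1:K; ib <- (K + 1):(2 * K)
  for (t in seq_len(TT - 1)) {
    Ut <- diag(u[t, ], K)
    Ext <- stats$Ex[, t, drop = FALSE]
    Ext1 <- stats$Ex[, t + 1, drop = FALSE]
    Szz[ia, ia] <- Szz[ia, ia] + Ut %*% stats$Exx[, , t] %*% Ut
    cross <- -Ut %*% Ext %*% u[t, , drop = FALSE]
    Szz[ia, ib] <- Szz[ia, ib] + cross
    Szz[ib, ia] <- Szz[ib, ia] + t(cross)
    Szz[ib, ib] <- Szz[ib, ib] + tcrossprod(u[t, ])
    Sdz[, ia] <- Sdz[, ia] + (stats$Exx1[, , t + 1] - stats$Exx[, , t]) %*% Ut
    Sdz[, ib] <- Sdz[, ib] - (Ext1 - Ext) %*% u[t, , drop = FALSE]
  }
  solve_or_stop <- function(M, rhs, what) {
    # rcond guards against numerically rank-deficient moment matrices (e.g.
    # a single transition cannot identify A and B jointly)
    out <- tryCatch({
      if (rcond(M) < 1e-10) NULL else t(solve(M, t(rhs)))
    }, error = function(e) NULL)
    if (is.null(out))
      stop("m_step: singular normal-equations matrix while updating ", what,
           "; provide more data or freeze parameters")
    out
  }
  a_frozen <- "A" %in% freeze
  b_frozen <- "B" %in% freeze
  if (a_frozen && b_frozen) {
    A <- prev$A; B <- prev$B
  } else if (!a_frozen && !b_frozen) {
    W <- -solve_or_stop(symm(Szz), Sdz, "(A, B)")
    A <- W[, ia, drop = FALSE]
    B <- W[, ib, drop = FALSE]
  } else if (a_frozen) {
    A <- prev$A
    # B Suu = sum_t (E[d_t] + A U_t E[x_t]) u_t'
    Suu <- Szz[ib, ib]
    rhs <- matrix(0, K, K)
    for (t in seq_len(TT - 1)) {
      Ut <- diag(u[t, ], K)
      d <- stats$Ex[, t + 1] - stats$Ex[, t] + drop(A %*% Ut %*% stats$Ex[, t])
      rhs <- rhs + tcrossprod(d, u[t, ])
    }
    B <- solve_or_stop(Suu, rhs, "B")
  } else {
    B <- prev$B
    # A sum U E[xx'] U = -sum (E[d_t z_a'] - B u_t E[x_t]' U_t)
    M <- Szz[ia, ia]
    rhs <- matrix(0, K, K)
    for (t in seq_len(TT - 1)) {
      Ut <- diag(u[t, ], K)
      rhs <- rhs + (stats$Exx1[, , t + 1] - stats$Exx[, , t]) %*% Ut -
        B %*% u[t, ] %*% t(stats$Ex[, t, drop = FALSE]) %*% Ut
    }
    A <- -solve_or_stop(M, rhs, "A")
  }
  W <- cbind(A, B)

  # -- Sigma_n from expected residual outer products ------------------------
  if ("Sigma_n" %in% freeze) {
    Sigma_n <- prev$Sigma_n
  } else {
    Sn <- matrix(0, K, K)
    for (t in seq_len(TT - 1)) {
      Ut <- diag(u[t, ], K)
      Ext <- stats$Ex[, t, drop = FALSE]
      Ext1 <- stats$Ex[, t + 1, drop = FALSE]
      Sdd <- stats$Exx[, , t + 1] - stats$Exx1[, , t + 1] -
        t(stats$Exx1[, , t + 1]) + stats$Exx[, , t]
      Szz_t <- matrix(0, 2 * K, 2 * K)
      Szz_t[ia, ia] <- Ut %*% stats$Exx[, , t] %*% Ut
      cr <- -Ut %*% Ext %*% u[t, , drop = FALSE]
      Szz_t[ia, ib] <- cr; Szz_t[ib, ia] <- t(cr)
      Szz_t[ib, ib] <- tcrossprod(u[t, ])
      Szd_t <- matrix(0, 2 * K, K)
      Szd_t[ia, ] <- Ut %*% (t(stats$Exx1[, , t + 1]) - stats$Exx[, , t])
      Szd_t[ib, ] <- -tcrossprod(u[t, ], drop(Ext1 - Ext))
      Sn <- Sn + Sdd + W %*% Szd_t + t(W %*% Szd_t) + W %*% Szz_t %*% t(W)
    }
    Sigma_n <- symm(Sn / (TT - 1))
  }

  # -- C and Sigma_w from observed days -------------------------------------
  if ("C" %in% freeze) {
    C <- prev$C
  } else {
    if (stats$n_obs == 0)
      stop("m_step: no observed days; cannot update C (freeze it instead)")
    C <- solve_or_stop(stats$S_xx_obs, stats$S_yx, "C")
  }
  if ("Sigma_w" %in% freeze) {
    Sigma_w <- prev$Sigma_w
  } else {
    sw <- (stats$S_yy - 2 * drop(C %*% t(stats$S_yx)) +
             drop(C %*% stats$S_xx_obs %*% t(C))) / max(stats$n_obs, 1)
    # floored at the filter's innovation floor; a floored coordinate is a
    # constrained M-step, which keeps EM monotone
    Sigma_w <- matrix(max(sw, .INNOV_FLOOR), 1, 1)
  }

  # -- initial state ---------------------------------------------------------
  mu_1 <- if ("mu_1" %in% freeze) prev$mu_1 else stats$Ex[, 1]
  if ("Sigma_1" %in% freeze) {
    Sigma_1 <- prev$Sigma_1
  } else {
    Sigma_1 <- symm(stats$Exx[, , 1] - tcrossprod(mu_1, stats$Ex[, 1]) -
                      tcrossprod(stats$Ex[, 1], mu_1) + tcrossprod(mu_1))
    ev <- eigen(Sigma_1, symmetric = TRUE)
    Sigma_1 <- symm(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
  }
  # clip tiny negative eigenvalues of Sigma_n arising from round-off
  evn <- eigen(Sigma_n, symmetric = TRUE)
  Sigma_n <- symm(evn$vectors %*% (pmax(evn$values, 0) * t(evn$vectors)))

  dbn_params(A = A, B = B, C = C, Sigma_n = Sigma_n, Sigma_w = Sigma_w,
             mu_1 = mu_1, Sigma_1 = Sigma_1)
}

# internal: expected complete-data log-likelihood Q(theta | stats), up to the
# additive constant -(T*K + n_obs)/2 * log(2*pi). Used by tests probing that
# m_step is the exact argmax.
q_fn <- function(params, stats, controls, obs) {
  K <- stats$K
  TT <- stats$T
  u <- controls$u
  ldet_psd <- function(M) {
    ev <- eigen(symm(M), symmetric = TRUE, only.values = TRUE)$values
    sum(log(pmax(ev, 1e-300)))
  }
  # initial state
  S1 <- stats$Exx[, , 1] - tcrossprod(params$mu_1, stats$Ex[, 1]) -
    tcrossprod(stats$Ex[, 1], params$mu_1) + tcrossprod(params$mu_1)
  iS1 <- solve_psd(params$Sigma_1, diag(K))
  q <- -0.5 * (ldet_psd(params$Sigma_1) + sum(iS1 * S1))
  # transitions
  W <- cbind(params$A, params$B)
  ia <- 1:K; ib <- (K + 1):(2 * K)
  iSn <- solve_psd(params$Sigma_n, diag(K))
  Rsum <- matrix(0, K, K)
  for (t in seq_len(TT - 1)) {
    Ut <- diag(u[t, ], K)
    Ext <- stats$Ex[, t, drop = FALSE]
    Ext1 <- stats$Ex[, t + 1, drop = FALSE]
    Sdd <- stats$Exx[, , t + 1] - stats$Exx1[, , t + 1] -
      t(stats$Exx1[, , t + 1]) + stats$Exx[, , t]
    Szz_t <- matrix(0, 2 * K, 2 * K)
    Szz_t[ia, ia] <- Ut %*% stats$Exx[, , t] %*% Ut
    cr <- -Ut %*% Ext %*% u[t, , drop = FALSE]
    Szz_t[ia, ib] <- cr; Szz_t[ib, ia] <- t(cr)
    Szz_t[ib, ib] <- tcrossprod(u[t, ])
    Szd_t <- matrix(0, 2 * K, K)
    Szd_t[ia, ] <- Ut %*% (t(stats$Exx1[, , t + 1]) - stats$Exx[, , t])
    Szd_t[ib, ] <- -tcrossprod(u[t, ], drop(Ext1 - Ext))
    Rsum <- Rsum + Sdd + W %*% Szd_t + t(W %*% Szd_t) + W %*% Szz_t %*% t(W)
  }
  q <- q - 0.5 * ((TT - 1) * ldet_psd(params$Sigma_n) + sum(iSn * Rsum))
  # emissions on observed days
  if (stats$n_obs > 0) {
    sw <- max(params$Sigma_w[1, 1], 1e-300)
    sse <- stats$S_yy - 2 * drop(params$C %*% t(stats$S_yx)) +
      drop(params$C %*% stats$S_xx_obs %*% t(params$C))
    q <- q - 0.5 * (stats$n_obs * log(sw) + sse / sw)
  }
  q
}

#' Fit the model by exact expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] from a starting point (typically
#' [build_initial_theta()]) until the marginal log-likelihood of the observed
#' data increases by less than `rel_tol` in relative terms (default 1 per
#' mille) or `max_iter` iterations are reached.
#'
#' The observed-data log-likelihood is non-decreasing along EM iterations;
#' a decrease beyond numerical tolerance signals an M-step defect and raises
#' an error rather than returning silently.
#'
#' @param theta0 starting [dbn_params()].
#' @param controls a [control_series()].
#' @param obs an [observation_series()] with at least 2 observed days.
#' @param max_iter iteration cap (default 100).
#' @param rel_tol relative log-likelihood increase below which iteration
#'   stops (default `1e-3`, i.e. 1 per mille); an absolute fallback of
#'   `1e-9` applies when the log-likelihood is near zero.
#' @param freeze parameter names passed through unchanged, see [m_step()].
#' @return An object of class `"em_trace"`: list with `loglik_per_iter`,
#'   `theta_final`, `n_iter`, `converged`.
#' @examples
#' ctl <- control_series(1:40, matrix(12, 40, 1))
#' th <- dbn_params(A = 0.01, B = 0.01, C = 1, Sigma_n = 1e-4,
#'                  Sigma_w = 1e-2, mu_1 = 20, Sigma_1 = 1e-3)
#' sim <- simulate_trajectory(th, ctl, seed = 42)
#' fit <- fit_em(th, ctl, sim$obs, max_iter = 20)
#' fit$n_iter
#' @export
fit_em <- function(theta0, controls, obs, max_iter = 100, rel_tol = 1e-3,
                   freeze = character()) {
  stopifnot(inherits(theta0, "dbn_params"))
  check_aligned(controls, obs)
  if (sum(obs$observed) < 2)
    stop("fit_em: need at least 2 observed measurements (",
         sum(obs$observed), " available)")
  theta <- theta0
  lls <- numeric(0)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    es <- e_step(theta, controls, obs)
    ll <- es$loglik
    if (!is.finite(ll)) stop("fit_em: non-finite log-likelihood at iteration ", i)
    if (length(lls) > 0 && ll < lls[length(lls)] - 1e-8 * max(1, abs(ll))) {
      dec <- lls[length(lls)] - ll
      # EM is monotone in exact arithmetic; near a degenerate optimum
      # (collapsing covariances on noise-free data) round-off can produce a
      # tiny dip, which signals numerical convergence, not an M-step bug
      if (dec <= 1e-3 * max(1, abs(ll))) {
        theta <- theta_prev   # the dipped update is discarded
        converged <- TRUE
        break
      }
      stop("fit_em: log-likelihood decreased at iteration ", i,
           " (", lls[length(lls)], " -> ", ll, "); M-step defect")
    }
    lls <- c(lls, ll)
    if (length(lls) > 1) {
      prev <- lls[length(lls) - 1]
      inc <- ll - prev
      rel <- if (abs(prev) > 1e-6) abs(inc) / abs(prev) else NA_real_
      if ((is.finite(rel) && rel < rel_tol) ||
          (!is.finite(rel) && abs(inc) < 1e-9)) {
        converged <- TRUE
        break
      }
    }
    theta_prev <- theta
    theta <- m_step(es$stats, controls, obs, freeze = freeze, prev = theta)
  }
  structure(list(loglik_per_iter = lls, theta_final = theta,
                 n_iter = length(lls), converged = converged),
            class = "em_trace")
}

#' @export
print.em_trace <- function(x, ...) {
  cat("EM trace:", x$n_iter, "iterations,",
      if (x$converged) "converged" else "iteration cap reached", "\n")
  cat("log-likelihood:", format(x$loglik_per_iter[1]), "->",
      format(x$loglik_per_iter[length(x$loglik_per_iter)]), "\n")
  invisible(x)
}
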