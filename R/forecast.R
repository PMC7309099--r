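# Multi-step-ahead prediction with frozen control.
#
# Control data are only available up to the forecast origin T, so the
# predictor freezes u_T and runs the state recursion freely, without
# response: x_{T+q} = (I - A U_T) x_{T+q-1} + B u_T, with the state
# covariance propagated by the same map plus state noise at every step.

#' q-step-ahead forecast under frozen control
#'
#' Starting from the smoothed posterior at the origin day, propagates the
#' state mean by \eqn{x_{T+j} = (I - A U_T) x_{T+j-1} + B u_T} and the state
#' covariance by \eqn{V_{T+j} = (I - A U_T) V_{T+j-1} (I - A U_T)^\top +
#' \Sigma_n}, then maps through the measurement matrix:
#' `y_mean = C x`, `y_var = C V C'`. The reported variance quantifies the
#' uncertainty of the measurement *mean* (state uncertainty propagated
#' through C); it does not add the single-day measurement noise.
#'
#' @param theta a [dbn_params()] object.
#' @param state_mean smoothed state mean at the origin day (length K).
#' @param state_cov smoothed state covariance at the origin day (K x K).
#' @param u_T control vector at the origin day, frozen for all steps.
#' @param q forecast horizon in days, >= 1.
#' @return An object of class `"dbn_forecast"`: list with `horizon_days`,
#'   `y_mean`, `y_var` (length q each), `state_mean` (q x K),
#'   `state_cov` (K x K x q).
#' @examples
#' th <- dbn_params(A = 0.01, B = 0.01, C = 1, Sigma_n = 1e-4,
#'                  Sigma_w = 1e-2, mu_1 = 20, Sigma_1 = 1e-3)
#' fc <- forecast(th, state_mean = 5, state_cov = matrix(0.1), u_T = 12, q = 21)
#' fc$y_mean[21]
#' @export
forecast <- function(theta, state_mean, state_cov, u_T, q) {
  stopifnot(inherits(theta, "dbn_params"))
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("forecast: 'q' must be a positive integer horizon")
  K <- theta$K
  state_mean <- as.numeric(state_mean)
  if (length(state_mean) != K)
    stop("forecast: 'state_mean' has length ", length(state_mean),
         " but K = ", K)
  state_cov <- as.matrix(state_cov)
  u_T <- as.numeric(u_T)
  if (length(u_T) != K) stop("forecast: 'u_T' has length ", length(u_T),
                             " but K = ", K)
  Ft <- diag(K) - theta$A %*% diag(u_T, K)
  cT <- drop(theta$B %*% u_T)
  sm <- matrix(NA_real_, q, K)
  sc <- array(NA_real_, c(K, K, q))
  y_mean <- numeric(q)
  y_var <- numeric(q)
  m <- state_mean
  V <- state_cov
  for (j in seq_len(q)) {
    m <- drop(Ft %*% m) + cT
    V <- symm(Ft %*% V %*% t(Ft) + theta$Sigma_n)
    sm[j, ] <- m
    sc[, , j] <- V
    y_mean[j] <- drop(theta$C %*% m)
    y_var[j] <- max(drop(theta$C %*% V %*% t(theta$C)), 0)
  }
  structure(list(horizon_days = q, y_mean = y_mean, y_var = y_var,
                 state_mean = sm, state_cov = sc),
            class = "dbn_forecast")
}

#' @export
print.dbn_forecast <- function(x, ...) {
  cat("Frozen-control forecast,", x$horizon_days, "day(s) ahead\n")
  print(utils::head(data.frame(step = seq_len(x$horizon_days),
                               y_mean = x$y_mean, y_sd = sqrt(x$y_var)), 10))
  if (x$horizon_days > 10) cat("...\n")
  invisible(x)
}

#' Back-transform a reciprocal-domain forecast to the indicator domain
#'
#' Returns the reciprocal of the forecast mean, `1 / y_mean`, per step. By
#' Jensen's inequality this is a *lower bound* of the indicator mean (the
#' reciprocal is convex on the positive axis), and the error variance of the
#' reciprocal of a Gaussian variable diverges, so no indicator-domain
#' variance is returned.
#'
#' @param fc a `"dbn_forecast"` with strictly positive `y_mean`.
#' @return A list with `indicator_point` (length q) and
#'   `bound = "jensen_lower"` flagging the interpretation.
#' @export
reciprocal_backtransform <- function(fc) {
  stopifnot(inherits(fc, "dbn_forecast"))
  if (any(fc$y_mean <= 0))
    stop("reciprocal_backtransform: non-positive reciprocal mean; ",
         "back-transformation undefined")
  list(indicator_point = 1 / fc$y_mean, bound = "jensen_lower")
}

#' Rolling q-step-ahead forecasts without future leakage
#'
#' For each forecast origin `T`, the model is re-fitted by EM on the data up
#' to `T` only (deterministic two-point initialization makes the refits
#' stable), the state posterior at `T` is smoothed, and a `q`-day
#' frozen-control forecast is issued. Origins earlier than the second
#' observed day are skipped. By construction no measurement after the origin
#' influences the forecast issued there.
#'
#' @param controls full-cycle [control_series()].
#' @param obs full-cycle [observation_series()] (model domain).
#' @param q horizon in days.
#' @param mode `"reciprocal_lai"` or `"et"` (drives initialization).
#' @param origins integer days at which to issue forecasts, or the string
#'   `"observed"` (default: every observed day from the second onward) or
#'   `"all"` (every day from the second observed day onward).
#' @param config an [init_config()].
#' @param freeze parameters to freeze during EM, see [m_step()].
#' @param max_iter,rel_tol EM settings, see [fit_em()].
#' @return A data.frame with one row per (origin, target) pair reaching into
#'   the cycle: columns `origin`, `target`, `q`, `y_mean`, `y_sd`, and
#'   `indicator_point` (back-transformed in reciprocal mode, `y_mean`
#'   otherwise). Attribute `"skipped"` lists skipped origins.
#' @export
rolling_forecast <- function(controls, obs, q, mode = c("reciprocal_lai", "et"),
                             origins = "observed", config = init_config(),
                             freeze = character(), max_iter = 100,
                             rel_tol = 1e-3) {
  mode <- match.arg(mode)
  check_aligned(controls, obs)
  if (q < 1) stop("rolling_forecast: 'q' must be >= 1")
  oi <- obs$times[obs$observed]
  if (length(oi) < 2)
    stop("rolling_forecast: need at least 2 observed days before forecasting")
  first_valid <- oi[2]
  if (identical(origins, "observed")) {
    origins <- oi
  } else if (identical(origins, "all")) {
    origins <- obs$times[obs$times >= first_valid]
  }
  skipped <- origins[origins < first_valid]
  origins <- origins[origins >= first_valid]
  rows <- vector("list", length(origins))
  for (k in seq_along(origins)) {
    To <- origins[k]
    idx <- which(obs$times <= To)
    ctl_T <- control_series(controls$times[idx],
                            controls$u[idx, , drop = FALSE], controls$delta)
    obs_T <- observation_series(obs$times[idx], obs$y[idx], obs$observed[idx])
    theta0 <- build_initial_theta(obs_T, ctl_T, mode = mode, config = config)
    # at very early origins the M-step normal equations can be singular
    # (fewer transitions than parameters); the two-point initialization is
    # already the exact interpolant there, so fall back to it
    theta_T <- tryCatch(
      fit_em(theta0, ctl_T, obs_T, max_iter = max_iter,
             rel_tol = rel_tol, freeze = freeze)$theta_final,
      error = function(e) {
        if (grepl("singular normal-equations", conditionMessage(e)))
          theta0
        else stop(e)
      })
    sp <- kalman_smooth(theta_T, ctl_T, obs_T)
    last <- length(idx)
    fc <- forecast(theta_T, sp$mean[last, ], sp$cov[, , last],
                   ctl_T$u[last, ], q)
    ind <- if (mode == "reciprocal_lai" && all(fc$y_mean > 0))
      reciprocal_backtransform(fc)$indicator_point else fc$y_mean
    rows[[k]] <- data.frame(origin = To, target = To + seq_len(q), q = q,
                            y_mean = fc$y_mean, y_sd = sqrt(fc$y_var),
                            indicator_point = ind)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
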