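#' Fit the crop-growth dynamic Bayesian network
#'
#' The main entry point: takes one cultivation cycle of daily data, builds
#' the control and observation series, initializes from the first two
#' observed measurements, fits all model parameters by exact EM with missing
#' days marginalized out, and smooths the hidden states. The fitted object
#' supports the usual verbs: `print`, `summary`, `coef`, `logLik`,
#' `fitted`, `residuals`, `predict` (frozen-control forecast), `simulate`
#' and `plot`.
#'
#' @param data a data.frame in the standard cycle schema (`gdt`, `temp_c`,
#'   `irradiance_mj`, optionally `gdd`, `y`, `observed`), or a list with
#'   ready-made `controls` and `obs` (model domain) as produced by
#'   [generate_growth_scenario()] or [read_series()].
#' @param mode `"reciprocal_lai"`: `y` is leaf area index and the model runs
#'   on its reciprocal; `"et"`: `y` is evapotranspiration, modelled directly.
#' @param freeze parameter names held at their initial values during EM
#'   (e.g. `"C"` to anchor the state scale to the all-one measurement map).
#' @param max_iter,rel_tol EM stopping rule: at most `max_iter` iterations
#'   (default 100) or a relative log-likelihood increase below `rel_tol`
#'   (default 1 per mille).
#' @param init an [init_config()].
#' @return An object of class `"cropdbn"`.
#' @examples
#' sc <- generate_growth_scenario(scenario_config(seed = 3))
#' fit <- cropdbn(sc, mode = "reciprocal_lai", freeze = "C")
#' coef(fit)$A
#' predict(fit, q = 21)$y_mean[21]
#' @export
cropdbn <- function(data, mode = c("reciprocal_lai", "et"),
                    freeze = character(), max_iter = 100, rel_tol = 1e-3,
                    init = init_config()) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.data.frame(data)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.csv(data, tmp, row.names = FALSE, na = "")
    parsed <- read_series(tmp, mode)
    controls <- parsed$controls
    obs <- parsed$obs
  } else if (is.list(data) && !is.null(data$controls) && !is.null(data$obs)) {
    controls <- data$controls
    obs <- data$obs
  } else {
    stop("cropdbn: 'data' must be a data.frame in the cycle schema or a ",
         "list with 'controls' and 'obs'")
  }
  theta0 <- build_initial_theta(obs, controls, mode = mode, config = init)
  fit <- fit_em(theta0, controls, obs, max_iter = max_iter,
                rel_tol = rel_tol, freeze = freeze)
  sp <- kalman_smooth(fit$theta_final, controls, obs)
  structure(list(theta = fit$theta_final, theta0 = theta0, trace = fit,
                 smoothed = sp, controls = controls, obs = obs, mode = mode,
                 freeze = freeze, init = init, call = cl),
            class = "cropdbn")
}

#' @export
print.cropdbn <- function(x, ...) {
  cat("Crop-growth state-space model (", x$mode, " mode)\n", sep = "")
  cat("  days:", length(x$obs$times), " observed:", sum(x$obs$observed), "\n")
  cat("  EM:", x$trace$n_iter, "iteration(s),",
      if (x$trace$converged) "converged" else "iteration cap reached", "\n")
  cat("  log-likelihood:", format(logLik(x)), "\n")
  invisible(x)
}

#' @export
summary.cropdbn <- function(object, ...) {
  res <- residuals(object)
  out <- list(mode = object$mode, n_days = length(object$obs$times),
              n_observed = sum(object$obs$observed),
              n_iter = object$trace$n_iter,
              converged = object$trace$converged,
              loglik = logLik(object), theta = object$theta,
              freeze = object$freeze,
              resid_summary = if (length(res) > 0) summary(res) else NULL)
  class(out) <- "summary.cropdbn"
  out
}

#' @export
print.summary.cropdbn <- function(x, ...) {
  cat("Crop-growth state-space model (", x$mode, " mode)\n", sep = "")
  cat("  days:", x$n_days, " observed:", x$n_observed, "\n")
  cat("  EM:", x$n_iter, "iteration(s),",
      if (x$converged) "converged" else "iteration cap reached",
      "; log-likelihood", format(x$loglik), "\n")
  if (length(x$freeze) > 0)
    cat("  frozen parameters:", paste(x$freeze, collapse = ", "), "\n")
  cat("\nParameters:\n")
  print(x$theta)
  if (!is.null(x$resid_summary)) {
    cat("\nInnovation residuals (observed days):\n")
    print(x$resid_summary)
  }
  invisible(x)
}

#' @export
coef.cropdbn <- function(object, ...) {
  th <- object$theta
  list(A = th$A, B = th$B, C = th$C, Sigma_n = th$Sigma_n,
       Sigma_w = th$Sigma_w[1, 1], mu_1 = th$mu_1, Sigma_1 = th$Sigma_1)
}

#' @export
logLik.cropdbn <- function(object, ...) {
  ll <- object$trace$loglik_per_iter[object$trace$n_iter]
  attr(ll, "df") <- with(object$theta,
                         2 * K^2 + K + K * (K + 1) + 1 + K)
  class(ll) <- "logLik"
  ll
}

#' @export
fitted.cropdbn <- function(object, ...) {
  drop(object$smoothed$mean %*% t(object$theta$C))
}

#' @export
residuals.cropdbn <- function(object, ...) {
  oi <- object$obs$observed
  (object$obs$y - fitted(object))[oi]
}

#' Forecast from a fitted model
#'
#' Frozen-control forecast `q` days past the end of the cycle (or past
#' `origin`), from the smoothed state posterior at the origin day.
#'
#' @param object a fitted [cropdbn()] model.
#' @param q horizon in days.
#' @param origin forecast origin day (default: last day of the cycle). When
#'   an earlier origin is given, the posterior still conditions on all data
#'   up to the cycle end; use [rolling_forecast()] for leakage-free
#'   evaluation protocols.
#' @param ... unused.
#' @return A `"dbn_forecast"` object with an `indicator_point` element added
#'   in reciprocal mode.
#' @export
predict.cropdbn <- function(object, q = 21, origin = NULL, ...) {
  times <- object$obs$times
  if (is.null(origin)) origin <- times[length(times)]
  i <- match(origin, times)
  if (is.na(i)) stop("predict.cropdbn: 'origin' outside the cycle")
  fc <- forecast(object$theta, object$smoothed$mean[i, ],
                 object$smoothed$cov[, , i], object$controls$u[i, ], q)
  if (object$mode == "reciprocal_lai" && all(fc$y_mean > 0))
    fc$indicator_point <- reciprocal_backtransform(fc)$indicator_point
  fc
}

#' Simulate cycles from a fitted model
#'
#' @param object a fitted [cropdbn()] model.
#' @param nsim number of simulated cycles.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` simulations as from [simulate_trajectory()].
#' @export
simulate.cropdbn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_trajectory(object$theta, object$controls))
}

#' Plot a fitted growth model
#'
#' Observed measurements, the smoothed state mapped through the measurement
#' matrix with a 95% band, and (optionally) a frozen-control forecast beyond
#' the cycle end, all in the model domain.
#'
#' @param x a fitted [cropdbn()] model.
#' @param q forecast horizon to append (0 for none).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cropdbn <- function(x, q = 0, ...) {
  times <- x$obs$times
  fit <- fitted(x)
  sd_fit <- sqrt(pmax(apply(x$smoothed$cov, 3, function(V)
    drop(x$theta$C %*% V %*% t(x$theta$C))), 0))
  xlim <- range(times)
  if (q > 0) xlim[2] <- xlim[2] + q
  ylim <- range(c(fit - 2 * sd_fit, fit + 2 * sd_fit,
                  x$obs$y[x$obs$observed]), na.rm = TRUE)
  graphics::plot(times, fit, type = "l", xlab = "growing day",
                 ylab = if (x$mode == "reciprocal_lai")
                   "reciprocal LAI" else "ET (mm/d)",
                 xlim = xlim, ylim = ylim, ...)
  graphics::polygon(c(times, rev(times)),
                    c(fit - 1.96 * sd_fit, rev(fit + 1.96 * sd_fit)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(times, fit)
  graphics::points(times[x$obs$observed], x$obs$y[x$obs$observed], pch = 16)
  if (q > 0) {
    fc <- predict(x, q = q)
    ft <- times[length(times)] + seq_len(q)
    graphics::lines(ft, fc$y_mean, lty = 2)
    graphics::lines(ft, fc$y_mean + 1.96 * sqrt(fc$y_var), lty = 3)
    graphics::lines(ft, fc$y_mean - 1.96 * sqrt(fc$y_var), lty = 3)
  }
  invisible(x)
}
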