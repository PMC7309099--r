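# Analytic reference models and transforms: the Boltzmann-sigmoid leaf area
# index model, the simplified radiation-based (Baille-type)
# evapotranspiration model, the logistic closed forms and their shared
# first-order difference equation, linear regression benchmarks, the growing
# degree day transform, and the prediction-error metric.

#' Parameters of the Boltzmann-sigmoid LAI model
#'
#' @param alpha,beta lower and upper LAI asymptotes (dimensionless),
#'   `beta > alpha`.
#' @param zeta inflection thermal time (degree-days).
#' @param delta thermal-time scale (degree-days), > 0.
#' @return A list of class `"carmassi_params"`.
#' @export
carmassi_params <- function(alpha, beta, zeta, delta) {
  if (beta <= alpha) stop("carmassi_params: need beta > alpha")
  if (delta <= 0) stop("carmassi_params: need delta > 0")
  structure(list(alpha = alpha, beta = beta, zeta = zeta, delta = delta),
            class = "carmassi_params")
}

#' Recalibrated sigmoid-LAI parameters for MicroTom (warm bright greenhouse)
#'
#' The constant set obtained by recalibrating the sigmoid LAI model on the
#' warm, brightly lit greenhouse environment (base temperature 10 degrees C):
#' alpha = 0.03, beta = 0.90, zeta = 560, delta = 50.
#' @return A [carmassi_params()] object.
#' @export
carmassi_env1 <- function() carmassi_params(0.03, 0.90, 560, 50)

#' Parameters of the simplified radiation-based ET model
#'
#' @param epsilon_b radiation-use regression coefficient (dimensionless).
#' @param gamma intercept (mm d-1).
#' @param k canopy light extinction coefficient (default 0.69).
#' @param lam latent heat of water vaporization (2.45 MJ kg-1).
#' @return A list of class `"baille_params"`.
#' @export
baille_params <- function(epsilon_b, gamma, k = 0.69, lam = 2.45) {
  if (k <= 0) stop("baille_params: need k > 0")
  if (lam <= 0) stop("baille_params: need lam > 0")
  structure(list(epsilon_b = epsilon_b, gamma = gamma, k = k, lam = lam),
            class = "baille_params")
}

#' Recalibrated simplified ET parameters for MicroTom
#'
#' epsilon = 0.109 and gamma = 0.32 mm d-1 (k = 0.69, lambda = 2.45).
#' @return A [baille_params()] object.
#' @export
baille_env1 <- function() baille_params(0.109, 0.32)

#' Growing degree days from mean daily temperature
#'
#' `max(mean_temp_c - base_c, 0)`: daily thermal time above a base
#' temperature of 10 degrees C (standard agronomic clamping at zero for days
#' below base).
#'
#' @param mean_temp_c mean daily temperature (degrees C); vectorized.
#' @param base_c base temperature (default 10).
#' @return Daily GDD (degree-days).
#' @examples
#' gdd_from_temperature(22.86)  # 12.86
#' @export
gdd_from_temperature <- function(mean_temp_c, base_c = 10) {
  if (any(!is.finite(mean_temp_c))) stop("gdd_from_temperature: non-finite input")
  pmax(mean_temp_c - base_c, 0)
}

#' Cumulative growing degree days
#'
#' Prefix sums of the daily GDD series (thermal time since transplantation).
#'
#' @param daily_gdd nonnegative daily GDD values.
#' @return Running cumulative sums, same length as the input.
#' @export
cumulative_gdd <- function(daily_gdd) {
  if (length(daily_gdd) == 0) return(numeric(0))
  if (any(daily_gdd < 0)) stop("cumulative_gdd: negative daily GDD entry")
  cumsum(daily_gdd)
}

#' Boltzmann-sigmoid LAI as a function of thermal time
#'
#' \eqn{\mathrm{LAI} = \alpha + (\beta - \alpha) /
#'   (1 + \exp\{(\zeta - \mathrm{cGDD})/\delta\})}.
#'
#' @param cum_gdd cumulative GDD (degree-days); vectorized.
#' @param p a [carmassi_params()] object.
#' @return LAI values in (alpha, beta).
#' @examples
#' carmassi_lai(560, carmassi_env1())  # midpoint (alpha + beta) / 2
#' @export
carmassi_lai <- function(cum_gdd, p = carmassi_env1()) {
  p$alpha + (p$beta - p$alpha) / (1 + exp((p$zeta - cum_gdd) / p$delta))
}

#' Simplified radiation-based daily evapotranspiration
#'
#' \eqn{ET = \epsilon (1 - e^{-k\,\mathrm{LAI}})\, R / \lambda + \gamma}
#' in mm d-1, with R the daily solar irradiance (MJ m-2 d-1).
#'
#' @param lai leaf area index, >= 0; vectorized.
#' @param R daily solar irradiance (MJ m-2 d-1), >= 0.
#' @param p a [baille_params()] object.
#' @return ET in mm d-1.
#' @export
baille_et <- function(lai, R, p = baille_env1()) {
  if (any(lai < 0)) stop("baille_et: negative LAI")
  if (any(R < 0)) stop("baille_et: negative irradiance")
  p$epsilon_b * (1 - exp(-p$k * lai)) * R / p$lam + p$gamma
}

#' Reciprocal-logistic closed form
#'
#' \eqn{x_t = \kappa (1 + e^{-\mu (t - t_0)})}: the reciprocal of the
#' logistic growth curve, strictly decreasing toward the steady state kappa,
#' and the solution of \eqn{dx/dt = -\mu x + \kappa \mu}.
#'
#' @param kappa steady state, > 0.
#' @param mu decay (day^-1), > 0.
#' @param t0 inflection day of the underlying logistic.
#' @param times evaluation days.
#' @return Numeric vector.
#' @export
reciprocal_logistic_series <- function(kappa, mu, t0, times) {
  if (kappa <= 0 || mu <= 0)
    stop("reciprocal_logistic_series: need kappa > 0 and mu > 0")
  kappa * (1 + exp(-mu * (times - t0)))
}

#' Logistic growth curve
#'
#' \eqn{z_t = [\kappa (1 + e^{-\mu (t - t_0)})]^{-1}}, the strictly
#' increasing sigmoid whose reciprocal obeys the linear first-order dynamics.
#'
#' @inheritParams reciprocal_logistic_series
#' @return Numeric vector.
#' @export
logistic_series <- function(kappa, mu, t0, times) {
  1 / reciprocal_logistic_series(kappa, mu, t0, times)
}

#' Saturating-exponential ET closed form
#'
#' \eqn{x_t = \kappa' (1 - e^{-\mu' t})}: same linear dynamics
#' \eqn{dx/dt = -\mu' x + \kappa' \mu'} as the reciprocal logistic, but with
#' initial condition \eqn{x_0 = 0}.
#'
#' @param kappa_p steady state (mm d-1), > 0.
#' @param mu_p rate (day^-1), > 0.
#' @param times evaluation days.
#' @return Numeric vector.
#' @export
et_closed_form <- function(kappa_p, mu_p, times) {
  if (kappa_p <= 0 || mu_p <= 0)
    stop("et_closed_form: need kappa_p > 0 and mu_p > 0")
  kappa_p * (1 - exp(-mu_p * times))
}

#' One Euler step of the shared growth dynamics
#'
#' \eqn{x_{t+\Delta} = x_t + \Delta(-\mu x_t + \kappa \mu)}: the first-order
#' linear ordinary difference equation underlying both closed forms; its
#' iterates converge to the exponential solution with O(Delta) error.
#'
#' @param x_t current value.
#' @param mu decay (day^-1).
#' @param kappa steady state.
#' @param delta time step (days), > 0.
#' @return Next value.
#' @export
difference_step <- function(x_t, mu, kappa, delta) {
  if (delta <= 0) stop("difference_step: 'delta' must be > 0")
  x_t + delta * (-mu * x_t + kappa * mu)
}

#' Linear-regression benchmark for LAI
#'
#' Ordinary least squares of the observed LAI on cumulative GDD,
#' \eqn{LAI_t = \rho_0 + \rho_1 \sum_{t' \le t} GDD_{t'} + \varepsilon_t},
#' fitted on observed days only (with exactly two observed points this is the
#' line through them).
#'
#' @param obs an [observation_series()] holding LAI (indicator domain).
#' @param cum_gdd cumulative GDD per day, aligned with `obs`.
#' @return A list of class `"lrm_params"`: `rho0`, `rho1`, `rho2` (NA for the
#'   LAI model), `resid_var`, and a `predict(newdata)` closure is not stored;
#'   use [predict_lrm()].
#' @export
fit_lrm_lai <- function(obs, cum_gdd) {
  stopifnot(inherits(obs, "observation_series"))
  if (length(cum_gdd) != length(obs$times))
    stop("fit_lrm_lai: 'cum_gdd' length mismatch")
  oi <- which(obs$observed)
  if (length(oi) < 2) stop("fit_lrm_lai: need >= 2 observed points")
  df <- data.frame(y = obs$y[oi], cgdd = cum_gdd[oi])
  if (length(unique(df$cgdd)) < 2)
    stop("fit_lrm_lai: rank-deficient design (constant cumulative GDD)")
  fit <- stats::lm(y ~ cgdd, data = df)
  co <- stats::coef(fit)
  rv <- if (length(oi) > 2) sum(stats::residuals(fit)^2) / (length(oi) - 2) else 0
  structure(list(rho0 = unname(co[1]), rho1 = unname(co[2]), rho2 = NA_real_,
                 resid_var = rv, kind = "lai"),
            class = "lrm_params")
}

#' Linear-regression benchmark for ET
#'
#' OLS of observed ET on cumulative GDD and daily irradiance,
#' \eqn{ET_t = \rho_0 + \rho_1 \sum_{t' \le t} GDD_{t'} + \rho_2 R_t +
#' \varepsilon_t}, on observed days only.
#'
#' @param obs an [observation_series()] holding ET (mm d-1).
#' @param cum_gdd cumulative GDD per day.
#' @param R daily solar irradiance per day (MJ m-2 d-1).
#' @return A `"lrm_params"` list with `rho0`, `rho1`, `rho2`, `resid_var`.
#' @export
fit_lrm_et <- function(obs, cum_gdd, R) {
  stopifnot(inherits(obs, "observation_series"))
  if (length(cum_gdd) != length(obs$times) || length(R) != length(obs$times))
    stop("fit_lrm_et: covariate length mismatch")
  oi <- which(obs$observed)
  if (length(oi) < 3) stop("fit_lrm_et: need >= 3 observed points")
  df <- data.frame(y = obs$y[oi], cgdd = cum_gdd[oi], R = R[oi])
  X <- cbind(1, df$cgdd, df$R)
  if (qr(X)$rank < 3) stop("fit_lrm_et: rank-deficient design")
  fit <- stats::lm(y ~ cgdd + R, data = df)
  co <- stats::coef(fit)
  rv <- if (length(oi) > 3) sum(stats::residuals(fit)^2) / (length(oi) - 3) else 0
  structure(list(rho0 = unname(co[1]), rho1 = unname(co[2]),
                 rho2 = unname(co[3]), resid_var = rv, kind = "et"),
            class = "lrm_params")
}

#' Predict from a fitted linear-regression benchmark
#'
#' @param p an `"lrm_params"` object.
#' @param cum_gdd cumulative GDD at the prediction days.
#' @param R daily irradiance (required for the ET model, ignored otherwise).
#' @return Predicted indicator values.
#' @export
predict_lrm <- function(p, cum_gdd, R = NULL) {
  stopifnot(inherits(p, "lrm_params"))
  if (p$kind == "lai") {
    p$rho0 + p$rho1 * cum_gdd
  } else {
    if (is.null(R)) stop("predict_lrm: ET model needs irradiance 'R'")
    p$rho0 + p$rho1 * cum_gdd + p$rho2 * R
  }
}

#' Average prediction error (percent)
#'
#' Mean absolute percentage error over observed comparison points:
#' \eqn{100 \cdot \mathrm{mean}(|pred - obs| / |obs|)}. Points with a zero
#' observation are skipped with a warning. `method = "rrmse"` instead returns
#' the root-mean-square error relative to the mean absolute observation,
#' in percent.
#'
#' @param pred predicted values.
#' @param obs observed values, same length.
#' @param mask logical; which points enter the comparison (default: all
#'   finite pairs).
#' @param method `"mape"` (default) or `"rrmse"`.
#' @return A percentage (scalar).
#' @examples
#' prediction_error_pct(c(1.1, 1.8), c(1, 2))  # 10
#' @export
prediction_error_pct <- function(pred, obs, mask = NULL,
                                 method = c("mape", "rrmse")) {
  method <- match.arg(method)
  if (length(pred) != length(obs))
    stop("prediction_error_pct: length mismatch")
  if (is.null(mask)) mask <- is.finite(pred) & is.finite(obs)
  mask <- as.logical(mask) & is.finite(pred) & is.finite(obs)
  if (!any(mask)) stop("prediction_error_pct: no comparison points")
  p <- pred[mask]; o <- obs[mask]
  if (method == "mape") {
    z <- o == 0
    if (any(z)) {
      warning("prediction_error_pct: skipping ", sum(z),
              " point(s) with zero observation")
      p <- p[!z]; o <- o[!z]
      if (length(o) == 0) stop("prediction_error_pct: no comparison points")
    }
    100 * mean(abs(p - o) / abs(o))
  } else {
    100 * sqrt(mean((p - o)^2)) / mean(abs(o))
  }
}

#' Recalibrate the analytic benchmark models on data
#'
#' Generic nonlinear least squares (via [stats::nls()] with a multi-start
#' fallback) for the sigmoid-LAI constants, and ordinary least squares for
#' the ET radiation-use coefficients given LAI.
#'
#' @param obs an [observation_series()] with the indicator (LAI or ET).
#' @param cum_gdd cumulative GDD per day (LAI model).
#' @param lai,R LAI and irradiance per day (ET model).
#' @param model `"carmassi"` or `"baille"`.
#' @return A [carmassi_params()] or [baille_params()] object.
#' @export
recalibrate_benchmark <- function(obs, cum_gdd = NULL, lai = NULL, R = NULL,
                                  model = c("carmassi", "baille")) {
  model <- match.arg(model)
  oi <- which(obs$observed)
  if (model == "carmassi") {
    if (is.null(cum_gdd)) stop("recalibrate_benchmark: 'cum_gdd' required")
    if (length(oi) < 4) stop("recalibrate_benchmark: need >= 4 observed points")
    df <- data.frame(y = obs$y[oi], g = cum_gdd[oi])
    st <- list(alpha = max(min(df$y), 1e-3), beta = max(df$y),
               zeta = stats::median(df$g), delta = diff(range(df$g)) / 6)
    fit <- stats::nls(y ~ alpha + (beta - alpha) / (1 + exp((zeta - g) / delta)),
                      data = df, start = st,
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    co <- stats::coef(fit)
    carmassi_params(co[["alpha"]], co[["beta"]], co[["zeta"]], co[["delta"]])
  } else {
    if (is.null(lai) || is.null(R))
      stop("recalibrate_benchmark: 'lai' and 'R' required")
    if (length(oi) < 2) stop("recalibrate_benchmark: need >= 2 observed points")
    # ET = eps * x + gamma with x = (1 - exp(-k lai)) R / lam: linear in eps
    x <- (1 - exp(-0.69 * lai[oi])) * R[oi] / 2.45
    fit <- stats::lm(obs$y[oi] ~ x)
    co <- stats::coef(fit)
    baille_params(unname(co[2]), unname(co[1]))
  }
}
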