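# EM starting point built from the first two observed measurements.
#
# The growth curve's closed forms make a two-point initialization possible:
# for reciprocal leaf area index the logistic decay mu has a closed form once
# the steady state kappa is fixed (kappa ~ 1 for MicroTom reciprocal LAI);
# for evapotranspiration the pair (kappa', mu') of the saturating exponential
# is found by a two-equation fixed point. The state matrix is then
# proportional to the decay, normalized by the sample mean of the control
# signal, and the control matrix is proportional to decay times steady state.

#' Initialization configuration
#'
#' @param eps small covariance scale used for the initial noise covariances
#'   (all set to `eps * I`); dimensionless, must be in (0, 1). Values of 0.1
#'   or above trigger a warning as suspiciously large.
#' @param kappa_fixed optional fixed steady state of the model-domain curve;
#'   defaults to 1 in `reciprocal_lai` mode (MicroTom) and is estimated in
#'   `et` mode when `NULL`.
#' @return A list of class `"init_config"`.
#' @export
init_config <- function(eps = 1e-3, kappa_fixed = NULL) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 1)
    stop("init_config: 'eps' must lie strictly between 0 and 1")
  structure(list(eps = eps, kappa_fixed = kappa_fixed), class = "init_config")
}

#' Initial noise covariances
#'
#' All three noise covariances start at `eps * I` with `eps` much smaller
#' than 1, so the first E-step trusts the deterministic two-point curve.
#'
#' @param K state dimension.
#' @param eps diagonal scale, in (0, 1).
#' @return A list with `Sigma_n`, `Sigma_w` (1 x 1) and `Sigma_1`.
#' @export
init_covariances <- function(K, eps) {
  if (K < 1) stop("init_covariances: K must be >= 1")
  if (eps >= 1 || eps <= 0) stop("init_covariances: 'eps' must be in (0, 1)")
  if (eps >= 0.1)
    warning("init_covariances: eps = ", eps,
            " is suspiciously large for a scale meant to be << 1")
  list(Sigma_n = diag(eps, K), Sigma_w = matrix(eps, 1, 1),
       Sigma_1 = diag(eps, K))
}

#' Initial measurement matrix (all ones)
#'
#' @param K state dimension.
#' @return A 1 x K matrix of ones.
#' @export
init_C <- function(K) {
  if (K < 1) stop("init_C: K must be >= 1")
  matrix(1, 1, K)
}

#' Initial state mean from the first observation
#'
#' Minimum-norm solution \eqn{\mu_1 = C^\top (C C^\top)^{-1} y_1} of the
#' underdetermined system \eqn{C \mu_1 = y_1}.
#'
#' @param C0 1 x K measurement matrix.
#' @param y1 first observed measurement.
#' @return Length-K vector satisfying `C0 %*% mu == y1` exactly.
#' @export
init_mu1 <- function(C0, y1) {
  C0 <- matrix(as.numeric(C0), nrow = 1)
  g <- drop(C0 %*% t(C0))
  if (g == 0) stop("init_mu1: measurement matrix is all-zero")
  drop(t(C0)) * (y1 / g)
}

#' Logistic decay and inflection from two points
#'
#' Inverts the reciprocal-logistic curve
#' \eqn{x_t = \kappa (1 + e^{-\mu (t - t_0)})} through two exact samples:
#' \deqn{\mu = \frac{\ln(y_2/\kappa - 1) - \ln(y_1/\kappa - 1)}{t_1 - t_2},
#'       \qquad t_0 = \frac{\ln(y_1/\kappa - 1) + \mu t_1}{\mu}.}
#'
#' @param y1,y2 measurements at days `t1`, `t2`; both must exceed `kappa`
#'   (the curve approaches its steady state from above).
#' @param t1,t2 distinct day indices.
#' @param kappa fixed steady state (e.g. 1 for MicroTom reciprocal LAI).
#' @return A list with `mu` (> 0) and `t0`.
#' @examples
#' logistic_mu_from_two_points(1 + exp(2), 1 + exp(1), 10, 20, kappa = 1)
#' @export
logistic_mu_from_two_points <- function(y1, y2, t1, t2, kappa) {
  if (t1 == t2) stop("logistic_mu_from_two_points: t1 and t2 coincide")
  if (y1 <= kappa || y2 <= kappa)
    stop("logistic_mu_from_two_points: observation at/below steady state; ",
         "cannot initialize")
  mu <- (log(y2 / kappa - 1) - log(y1 / kappa - 1)) / (t1 - t2)
  if (!is.finite(mu) || mu <= 0)
    stop("logistic_mu_from_two_points: non-positive decay (mu = ",
         format(mu), "); observations do not decrease toward the steady state")
  t0 <- (log(y1 / kappa - 1) + mu * t1) / mu
  list(mu = mu, t0 = t0)
}

#' Steady state from a third point of the logistic curve
#'
#' Solves \eqn{\kappa = y_3 (1 + e^{-\mu (t_3 - t_0)})^{-1}} ... rearranged,
#' given (mu, t0) from the two-point solver, the third equation of the
#' nonlinear system returns the steady state implied by a third sample.
#' Unused by the default pipeline (kappa is fixed a priori) but kept for
#' generality.
#'
#' @param y3 measurement at day `t3`.
#' @param t3 day index.
#' @param mu,t0 decay and inflection from [logistic_mu_from_two_points()].
#' @return Scalar kappa.
#' @export
logistic_kappa_from_third_point <- function(y3, t3, mu, t0) {
  y3 / (1 + exp(-mu * (t3 - t0)))
}

#' Saturating-exponential parameters from two points (fixed point)
#'
#' Inverts the evapotranspiration curve \eqn{x_t = \kappa'(1 - e^{-\mu' t})}
#' through two samples by alternating
#' \deqn{\mu' = -\frac{1}{t_1}\ln(1 - y_1/\kappa'), \qquad
#'       \kappa' = \frac{y_2}{1 - e^{-\mu' t_2}}}
#' until the relative change in \eqn{\kappa'} drops below `tol`. The iterate
#' starts at \eqn{\kappa'^{(0)} = 1.05\, y_2} (it must exceed the data for
#' the logarithm to exist).
#'
#' @param y1,y2 measurements at days `t1 < t2`, with `0 < y1 < y2`.
#' @param t1,t2 day indices, `t1 > 0`.
#' @param tol relative convergence tolerance on kappa'.
#' @param max_iter iteration cap.
#' @return A list with `kappa_p`, `mu_p` and `n_iter`.
#' @examples
#' et_params_from_two_points(2 * (1 - exp(-0.5)), 2 * (1 - exp(-2)), 10, 40)
#' @export
et_params_from_two_points <- function(y1, y2, t1, t2, tol = 1e-8,
                                      max_iter = 1000) {
  if (!(t1 > 0 && t1 < t2)) stop("et_params_from_two_points: need 0 < t1 < t2")
  if (!(y1 > 0 && y1 < y2))
    stop("et_params_from_two_points: need 0 < y1 < y2 (growing curve)")
  kp <- 1.05 * y2
  mu_p <- NA_real_
  step <- function(k) {
    if (y1 >= k)
      stop("et_params_from_two_points: iterate kappa' = ", format(k),
           " fell to/below y1; curve inconsistent with a saturating exponential")
    m <- -log(1 - y1 / k) / t1
    k_new <- y2 / (1 - exp(-m * t2))
    if (!is.finite(k_new) || k_new <= 0)
      stop("et_params_from_two_points: fixed point diverged")
    k_new
  }
  for (i in seq_len(max_iter)) {
    # Aitken-accelerated (Steffensen) fixed point: the plain iteration
    # contracts arbitrarily slowly when the two samples sit close together
    k1 <- step(kp)
    k2 <- step(k1)
    den <- k2 - 2 * k1 + kp
    kp_new <- if (abs(den) > .Machine$double.eps * max(1, abs(k2)))
      kp - (k1 - kp)^2 / den else k2
    if (!is.finite(kp_new) || kp_new <= y1) kp_new <- k2
    if (abs(kp_new - kp) / kp < tol) {
      kp <- kp_new
      mu_p <- -log(1 - y1 / kp) / t1
      # consistency check: both inputs must be reproduced by the curve
      r1 <- kp * (1 - exp(-mu_p * t1))
      r2 <- kp * (1 - exp(-mu_p * t2))
      if (abs(r1 - y1) > 100 * tol * max(1, y1) ||
          abs(r2 - y2) > 100 * tol * max(1, y2))
        stop("et_params_from_two_points: converged iterate does not ",
             "reproduce the input points")
      return(list(kappa_p = kp, mu_p = mu_p, n_iter = i))
    }
    kp <- kp_new
  }
  stop("et_params_from_two_points: no convergence in ", max_iter,
       " iterations; last kappa' = ", format(kp), ", mu' = ", format(mu_p))
}

#' Initial state matrix from the decay
#'
#' \eqn{A^{(0)} = \mu \, \mathrm{diag}(\bar u)^{-1}}: the state matrix is
#' proportional to the decay, normalized component-wise by the sample mean of
#' the control signal.
#'
#' @param mu decay rate (day^-1).
#' @param controls a [control_series()].
#' @return K x K diagonal matrix.
#' @export
init_A <- function(mu, controls) {
  ubar <- colMeans(controls$u)
  if (any(ubar == 0))
    stop("init_A: control component with zero sample mean; cannot normalize")
  diag(mu / ubar, ncol(controls$u))
}

#' Initial control matrix from decay and steady state
#'
#' \eqn{B^{(0)} = A^{(0)} \kappa}.
#'
#' @param A0 K x K initial state matrix.
#' @param kappa steady state.
#' @return K x K matrix.
#' @export
init_B <- function(A0, kappa) A0 * kappa

#' Compose the full EM starting point
#'
#' Builds \eqn{\theta^{(0)}} from the first two observed measurements (in
#' time order): noise covariances at `eps * I`, all-one measurement matrix,
#' minimum-norm initial mean matching the first observation, and `(A, B)`
#' from the mode-specific two-point curve inversion.
#'
#' @param obs an [observation_series()] with at least 2 observed days, in the
#'   model domain (reciprocal LAI or ET).
#' @param controls the aligned [control_series()].
#' @param mode `"reciprocal_lai"` (fixed steady state, default 1) or `"et"`
#'   (two-point fixed-point solver).
#' @param config an [init_config()].
#' @return A [dbn_params()] object.
#' @export
build_initial_theta <- function(obs, controls,
                                mode = c("reciprocal_lai", "et"),
                                config = init_config()) {
  mode <- match.arg(mode)
  check_aligned(controls, obs)
  oi <- which(obs$observed)
  if (length(oi) < 2)
    stop("build_initial_theta: need at least 2 observed measurements (",
         length(oi), " available)")
  t1 <- obs$times[oi[1]]; y1 <- obs$y[oi[1]]
  t2 <- obs$times[oi[2]]; y2 <- obs$y[oi[2]]
  K <- ncol(controls$u)
  covs <- init_covariances(K, config$eps)
  C0 <- init_C(K)
  mu1 <- init_mu1(C0, y1)
  if (mode == "reciprocal_lai") {
    kappa <- if (is.null(config$kappa_fixed)) 1 else config$kappa_fixed
    sol <- logistic_mu_from_two_points(y1, y2, t1, t2, kappa)
    mu <- sol$mu
  } else {
    sol <- et_params_from_two_points(y1, y2, t1, t2)
    kappa <- sol$kappa_p
    mu <- sol$mu_p
  }
  A0 <- init_A(mu, controls)
  # per-component steady state kappa / K: under the all-one measurement
  # matrix the emitted measurement then settles at kappa itself
  B0 <- init_B(A0, kappa / K)
  dbn_params(A = A0, B = B0, C = C0, Sigma_n = covs$Sigma_n,
             Sigma_w = covs$Sigma_w, mu_1 = mu1, Sigma_1 = covs$Sigma_1)
}
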