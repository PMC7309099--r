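#' Daily control series
#'
#' Container for the per-day control vectors \eqn{u_t} that drive the state
#' transition of the growth model. Controls are deterministic functions of
#' the greenhouse environment (e.g. daily growing degree days, daily solar
#' irradiance) and must be complete: the model marginalizes missing
#' *measurements*, never missing controls.
#'
#' @param times integer growing days after transplantation (GDT), 1-based and
#'   consecutive with unit step.
#' @param u numeric matrix with one row per day and \eqn{K \ge 1} columns
#'   (a vector is taken as a single-column matrix). Units depend on the
#'   mapping, e.g. degree-days for a GDD component, MJ m-2 d-1 for an
#'   irradiance component.
#' @param delta time granularity in days. The model is formulated at daily
#'   granularity; `delta` is carried for generality and defaults to 1.
#'
#' @return An object of class `"control_series"`: a list with elements
#'   `times`, `u` (T x K matrix) and `delta`.
#' @examples
#' ctl <- control_series(1:5, matrix(12.86, 5, 1))
#' ctl$u
#' @export
control_series <- function(times, u, delta = 1) {
  if (is.vector(u) && is.numeric(u)) u <- matrix(u, ncol = 1)
  u <- as.matrix(u)
  storage.mode(u) <- "double"
  times <- as.integer(times)
  if (length(times) != nrow(u))
    stop("control_series: 'times' length (", length(times),
         ") does not match rows of 'u' (", nrow(u), ")")
  if (length(times) == 0L) stop("control_series: empty series")
  if (anyNA(u) || any(!is.finite(u)))
    stop("control_series: 'u' must be finite with no missing entries")
  if (length(times) > 1L && any(diff(times) != 1L))
    stop("control_series: 'times' must be strictly increasing with unit step")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("control_series: 'delta' must be a positive scalar")
  structure(list(times = times, u = u, delta = as.numeric(delta)),
            class = "control_series")
}

#' Scalar observation series with missingness mask
#'
#' Daily measurements \eqn{y_t} of a growth indicator in the *model* domain:
#' the reciprocal leaf area index (dimensionless) in `reciprocal_lai` mode,
#' or evapotranspiration (mm d-1) in `et` mode. Days with `observed = FALSE`
#' carry no information (their `y` may be `NA`) and are integrated out of the
#' likelihood, the missing-at-random route.
#'
#' @param times integer GDT days, aligned to a [control_series()].
#' @param y numeric measurements; may be `NA` on unobserved days.
#' @param observed logical mask, one entry per day.
#'
#' @return An object of class `"observation_series"`.
#' @examples
#' obs <- observation_series(1:4, c(3, NA, 2, NA), c(TRUE, FALSE, TRUE, FALSE))
#' sum(obs$observed)
#' @export
observation_series <- function(times, y, observed = !is.na(y)) {
  times <- as.integer(times)
  y <- as.numeric(y)
  observed <- as.logical(observed)
  if (length(y) != length(times) || length(observed) != length(times))
    stop("observation_series: 'times', 'y' and 'observed' lengths differ")
  if (anyNA(observed)) stop("observation_series: 'observed' must not contain NA")
  if (any(observed & !is.finite(y)))
    stop("observation_series: 'y' must be finite wherever observed")
  if (length(times) > 1L && any(diff(times) != 1L))
    stop("observation_series: 'times' must be strictly increasing with unit step")
  structure(list(times = times, y = y, observed = observed),
            class = "observation_series")
}

#' Parameters of the growth state-space model
#'
#' Bundles \eqn{\theta = \{A, B, C, \Sigma_n, \Sigma_w, \mu_1, \Sigma_1\}} of
#' the linear-Gaussian dynamic Bayesian network
#' \deqn{x_{t+1} \sim N((I - A U_t) x_t + B u_t, \Sigma_n), \quad
#'       y_t \sim N(C x_t, \Sigma_w), \quad x_1 \sim N(\mu_1, \Sigma_1)}
#' with \eqn{U_t = \mathrm{diag}(u_t)}. Covariance blocks are symmetrized
#' on construction and validated for positive semi-definiteness.
#'
#' @param A K x K state matrix (per-day decay per control unit).
#' @param B K x K control matrix.
#' @param C 1 x K measurement matrix (a vector is coerced).
#' @param Sigma_n K x K state-noise covariance, symmetric PSD.
#' @param Sigma_w scalar (1 x 1) measurement-noise variance, >= 0.
#' @param mu_1 length-K initial state mean.
#' @param Sigma_1 K x K initial state covariance, symmetric PSD.
#'
#' @return An object of class `"dbn_params"`.
#' @examples
#' th <- dbn_params(A = 0.01, B = 0.01, C = 1, Sigma_n = 1e-4,
#'                  Sigma_w = 1e-2, mu_1 = 30, Sigma_1 = 1e-3)
#' th$A
#' @export
dbn_params <- function(A, B, C, Sigma_n, Sigma_w, mu_1, Sigma_1) {
  as_sq <- function(M, nm) {
    if (is.null(dim(M))) M <- diag(as.numeric(M), nrow = length(M))
    M <- as.matrix(M)
    if (nrow(M) != ncol(M)) stop("dbn_params: '", nm, "' must be square")
    storage.mode(M) <- "double"
    M
  }
  # scalars become 1x1 so K = 1 models can be written without matrix()
  if (length(A) == 1L && is.null(dim(A))) A <- matrix(A, 1, 1)
  if (length(B) == 1L && is.null(dim(B))) B <- matrix(B, 1, 1)
  A <- as_sq(A, "A"); B <- as_sq(B, "B")
  K <- nrow(A)
  C <- matrix(as.numeric(C), nrow = 1)
  if (ncol(C) != K) stop("dbn_params: 'C' must have ", K, " columns")
  if (length(Sigma_n) == 1L && is.null(dim(Sigma_n))) Sigma_n <- diag(Sigma_n, K)
  Sigma_n <- as_sq(Sigma_n, "Sigma_n")
  Sigma_w <- matrix(as.numeric(Sigma_w), 1, 1)
  mu_1 <- as.numeric(mu_1)
  if (length(Sigma_1) == 1L && is.null(dim(Sigma_1))) Sigma_1 <- diag(Sigma_1, K)
  Sigma_1 <- as_sq(Sigma_1, "Sigma_1")
  if (ncol(B) != K || nrow(B) != K) stop("dbn_params: 'B' must be ", K, " x ", K)
  if (nrow(Sigma_n) != K) stop("dbn_params: 'Sigma_n' must be ", K, " x ", K)
  if (length(mu_1) != K) stop("dbn_params: 'mu_1' must have length ", K)
  if (nrow(Sigma_1) != K) stop("dbn_params: 'Sigma_1' must be ", K, " x ", K)
  check_psd <- function(M, nm) {
    if (max(abs(M - t(M))) > 1e-10)
      stop("dbn_params: '", nm, "' is not symmetric (within 1e-10)")
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev))))
      stop("dbn_params: '", nm, "' is not positive semi-definite")
  }
  Sigma_n <- (Sigma_n + t(Sigma_n)) / 2
  Sigma_1 <- (Sigma_1 + t(Sigma_1)) / 2
  check_psd(Sigma_n, "Sigma_n")
  check_psd(Sigma_1, "Sigma_1")
  if (Sigma_w[1, 1] < 0) stop("dbn_params: 'Sigma_w' must be >= 0")
  structure(list(A = A, B = B, C = C, Sigma_n = Sigma_n, Sigma_w = Sigma_w,
                 mu_1 = mu_1, Sigma_1 = Sigma_1, K = K),
            class = "dbn_params")
}

#' @export
print.dbn_params <- function(x, ...) {
  cat("Growth state-space parameters (K =", x$K, ")\n")
  cat("A:\n"); print(x$A)
  cat("B:\n"); print(x$B)
  cat("C:", format(x$C), "\n")
  cat("Sigma_n diag:", format(diag(x$Sigma_n)), "\n")
  cat("Sigma_w:", format(x$Sigma_w[1, 1]), "\n")
  cat("mu_1:", format(x$mu_1), "\n")
  cat("Sigma_1 diag:", format(diag(x$Sigma_1)), "\n")
  invisible(x)
}

# internal: validate that controls and observations cover the same days
check_aligned <- function(controls, obs) {
  stopifnot(inherits(controls, "control_series"),
            inherits(obs, "observation_series"))
  if (length(controls$times) != length(obs$times) ||
      any(controls$times != obs$times))
    stop("control and observation series are misaligned (different days)")
  invisible(TRUE)
}

# internal: validate parameter/control dimension agreement
check_dims <- function(params, controls) {
  if (params$K != ncol(controls$u))
    stop("parameter dimension K = ", params$K,
         " does not match control dimension ", ncol(controls$u))
  invisible(TRUE)
}

# internal: indicator <-> model domain maps. The model operates on 1/LAI in
# reciprocal_lai mode and directly on ET in et mode.
to_model_domain <- function(y, mode) {
  mode <- match.arg(mode, c("reciprocal_lai", "et"))
  if (mode == "reciprocal_lai") {
    if (any(!is.na(y) & y <= 0))
      stop("reciprocal_lai mode requires positive indicator values")
    ifelse(is.na(y), NA_real_, 1 / y)
  } else y
}

to_indicator_domain <- function(y, mode) {
  mode <- match.arg(mode, c("reciprocal_lai", "et"))
  if (mode == "reciprocal_lai") ifelse(is.na(y), NA_real_, 1 / y) else y
}

# internal: symmetrize a covariance to suppress round-off drift
symm <- function(M) (M + t(M)) / 2
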