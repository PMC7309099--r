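# CSV readers/writers and parameter serialization.
#
# CSV schema, one row per growing day after transplantation:
#   gdt, temp_c, irradiance_mj, gdd, y, observed(0/1)
# The y column carries the growth indicator in its natural units (LAI
# dimensionless, ET in mm d-1); missing y is an empty field with observed=0.
# The gdd column is computed from temp_c (base 10 degrees C) when absent.

#' Read a cultivation-cycle CSV
#'
#' Parses the standard schema, validates it, derives the missingness mask
#' from the `observed` flag (empty `y` cells are missing), computes daily GDD
#' from temperature when the `gdd` column is absent, and returns the control
#' and observation series. Observations are mapped to the model domain
#' (reciprocal for `reciprocal_lai` mode).
#'
#' @param path CSV file path.
#' @param mode `"reciprocal_lai"` or `"et"`.
#' @return A list with `controls` ([control_series()]; K = 1 GDD for
#'   `reciprocal_lai`, K = 2 GDD+irradiance for `et`), `obs`
#'   ([observation_series()], model domain), and the raw `data` frame.
#' @export
read_series <- function(path, mode = c("reciprocal_lai", "et")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("read_series: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gdt", "temp_c", "irradiance_mj", "y", "observed")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_series: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$gdt) | !is.finite(df$temp_c) |
                 !is.finite(df$irradiance_mj) | !(df$observed %in% c(0, 1)))
  if (length(bad) > 0)
    stop("read_series: malformed row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  if (nrow(df) > 1 && any(diff(df$gdt) != 1))
    stop("read_series: non-consecutive GDT days in ", path)
  if (!"gdd" %in% names(df) || all(is.na(df$gdd)))
    df$gdd <- gdd_from_temperature(df$temp_c)
  observed <- df$observed == 1 & !is.na(df$y)
  y_model <- to_model_domain(df$y, mode)
  u <- if (mode == "reciprocal_lai") cbind(gdd = df$gdd)
       else cbind(gdd = df$gdd, irradiance = df$irradiance_mj)
  list(controls = control_series(df$gdt, u),
       obs = observation_series(df$gdt, ifelse(observed, y_model, NA_real_),
                                observed),
       data = df)
}

#' Write a cultivation cycle to CSV
#'
#' Inverse of [read_series()]: observations are mapped back to the indicator
#' domain and missing days written as empty `y` with `observed = 0`.
#'
#' @param controls a [control_series()] (first column daily GDD; second,
#'   if present, daily irradiance).
#' @param obs an aligned [observation_series()] in the model domain.
#' @param path output CSV path.
#' @param mode `"reciprocal_lai"` or `"et"`.
#' @param temp_c optional temperature column; reconstructed as `gdd + 10`
#'   when omitted.
#' @param irradiance_mj optional irradiance column (required when `controls`
#'   has a single column and the file should carry irradiance).
#' @return The path, invisibly.
#' @export
write_series <- function(controls, obs, path,
                         mode = c("reciprocal_lai", "et"),
                         temp_c = NULL, irradiance_mj = NULL) {
  mode <- match.arg(mode)
  check_aligned(controls, obs)
  gdd <- controls$u[, 1]
  if (is.null(temp_c)) temp_c <- gdd + 10
  if (is.null(irradiance_mj))
    irradiance_mj <- if (ncol(controls$u) >= 2) controls$u[, 2] else
      rep(0, length(gdd))
  y_ind <- to_indicator_domain(obs$y, mode)
  df <- data.frame(gdt = controls$times, temp_c = temp_c,
                   irradiance_mj = irradiance_mj, gdd = gdd,
                   y = ifelse(obs$observed, y_ind, NA_real_),
                   observed = as.integer(obs$observed))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize fitted parameters to JSON
#'
#' Writes theta with dimensions and operating mode recorded, readable back
#' with [read_theta()].
#'
#' @param theta a [dbn_params()].
#' @param path output path.
#' @param mode operating mode recorded in the file.
#' @return The path, invisibly.
#' @export
write_theta <- function(theta, path, mode = "reciprocal_lai") {
  stopifnot(inherits(theta, "dbn_params"))
  obj <- list(K = theta$K, mode = mode,
              A = theta$A, B = theta$B, C = theta$C,
              Sigma_n = theta$Sigma_n, Sigma_w = theta$Sigma_w,
              mu_1 = theta$mu_1, Sigma_1 = theta$Sigma_1)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read fitted parameters from JSON
#'
#' @param path a file written by [write_theta()].
#' @return A list with `theta` ([dbn_params()]) and `mode`.
#' @export
read_theta <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(M, K) {
    if (is.matrix(M)) return(as.matrix(M))
    matrix(as.numeric(unlist(M)), K, K, byrow = TRUE)
  }
  K <- obj$K
  theta <- dbn_params(A = as_mat(obj$A, K), B = as_mat(obj$B, K),
                      C = as.numeric(unlist(obj$C)),
                      Sigma_n = as_mat(obj$Sigma_n, K),
                      Sigma_w = as.numeric(unlist(obj$Sigma_w)),
                      mu_1 = as.numeric(unlist(obj$mu_1)),
                      Sigma_1 = as_mat(obj$Sigma_1, K))
  list(theta = theta, mode = obj$mode)
}
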