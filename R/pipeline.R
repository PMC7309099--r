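# End-to-end pipeline and command-line surface.

#' Run configuration
#'
#' @param mode `"reciprocal_lai"` or `"et"`; must be set explicitly by
#'   callers that read real data (the generator records it itself).
#' @param q forecast horizon in days (>= 1).
#' @param max_iter,rel_tol EM settings: iteration cap 100 and 1-per-mille
#'   relative log-likelihood increase by default.
#' @param freeze parameters frozen during EM (e.g. `"C"`).
#' @param metric `"mape"` or `"rrmse"`, see [prediction_error_pct()].
#' @param eps initialization covariance scale.
#' @param kappa_fixed fixed steady state for reciprocal-LAI initialization.
#' @param origins forecast origins, see [rolling_forecast()].
#' @param seed integer seed recorded in the manifest.
#' @param data_path input CSV (omit when a scenario is generated in-process).
#' @param out_dir output directory; one directory per run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(mode = c("reciprocal_lai", "et"), q = 21,
                       max_iter = 100, rel_tol = 1e-3, freeze = character(),
                       metric = c("mape", "rrmse"), eps = 1e-3,
                       kappa_fixed = NULL, origins = "observed", seed = 1L,
                       data_path = NULL, out_dir = tempfile("cropdbn_run_")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (q < 1) stop("run_config: 'q' must be >= 1")
  if (rel_tol <= 0) stop("run_config: 'rel_tol' must be > 0")
  structure(list(mode = mode, q = as.integer(q), max_iter = max_iter,
                 rel_tol = rel_tol, freeze = freeze, metric = metric,
                 eps = eps, kappa_fixed = kappa_fixed, origins = origins,
                 seed = as.integer(seed), data_path = data_path,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0)
    stop("read_run_config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Execute the full analysis pipeline
#'
#' read data -> two-point initialization -> EM fit -> rolling q-step
#' forecasts -> error metrics -> benchmark comparison (sigmoid-LAI /
#' radiation-ET analytic model and the linear regression model), writing all
#' artifacts into `config$out_dir`: `theta.json`, `em_trace.csv`,
#' `smoothed.csv`, `forecasts.csv`, `error_summary.csv` and `manifest.yaml`.
#'
#' @param config a [run_config()] with `data_path` set, or `data` supplied.
#' @param data optional list with `controls` and `obs` (model domain),
#'   bypassing `data_path`.
#' @return Invisibly, a list with the fitted model pieces and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(data)) {
    if (is.null(config$data_path))
      stop("run_pipeline: neither 'data' nor config$data_path supplied")
    data <- stage("read", read_series(config$data_path, config$mode))
  }
  controls <- data$controls
  obs <- data$obs
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  icfg <- init_config(eps = config$eps, kappa_fixed = config$kappa_fixed)
  theta0 <- stage("init",
                  build_initial_theta(obs, controls, mode = config$mode,
                                      config = icfg))
  message("cropdbn: initial A diag = ",
          paste(format(diag(theta0$A)), collapse = ", "),
          "; B diag = ", paste(format(diag(theta0$B)), collapse = ", "))
  fit <- stage("fit_em",
               fit_em(theta0, controls, obs, max_iter = config$max_iter,
                      rel_tol = config$rel_tol, freeze = config$freeze))
  message("cropdbn: EM ", fit$n_iter, " iteration(s), loglik ",
          format(fit$loglik_per_iter[fit$n_iter]))
  sp <- kalman_smooth(fit$theta_final, controls, obs)
  fcs <- stage("rolling_forecast",
               rolling_forecast(controls, obs, q = config$q,
                                mode = config$mode, origins = config$origins,
                                config = icfg, freeze = config$freeze,
                                max_iter = config$max_iter,
                                rel_tol = config$rel_tol))
  # q-step-ahead prediction vs observation at the target day
  fq <- fcs[fcs$target == fcs$origin + config$q &
              fcs$target <= max(obs$times), , drop = FALSE]
  err <- stage("metrics", {
    idx <- match(fq$target, obs$times)
    ok <- !is.na(idx) & obs$observed[idx]
    dbn_err <- if (any(ok))
      prediction_error_pct(fq$y_mean[ok], obs$y[idx[ok]],
                           method = config$metric) else NA_real_
    cg <- cumulative_gdd(controls$u[, 1])
    y_ind <- to_indicator_domain(obs$y, config$mode)
    obs_ind <- observation_series(obs$times, y_ind, obs$observed)
    if (config$mode == "reciprocal_lai") {
      bench_pred <- carmassi_lai(cg)
      lrm <- fit_lrm_lai(obs_ind, cg)
      lrm_pred <- predict_lrm(lrm, cg)
    } else {
      irr <- if (ncol(controls$u) >= 2) controls$u[, 2] else
        rep(0, length(cg))
      bench_pred <- baille_et(carmassi_lai(cg), irr)
      lrm <- fit_lrm_et(obs_ind, cg, irr)
      lrm_pred <- predict_lrm(lrm, cg, irr)
    }
    oo <- obs_ind$observed
    data.frame(
      model = c("dbn", "carmassi", "lrm"),
      error_pct = c(dbn_err,
                    prediction_error_pct(bench_pred[oo], y_ind[oo],
                                         method = config$metric),
                    prediction_error_pct(lrm_pred[oo], y_ind[oo],
                                         method = config$metric)))
  })
  paths <- list(theta = file.path(config$out_dir, "theta.json"),
                em_trace = file.path(config$out_dir, "em_trace.csv"),
                smoothed = file.path(config$out_dir, "smoothed.csv"),
                forecasts = file.path(config$out_dir, "forecasts.csv"),
                error_summary = file.path(config$out_dir, "error_summary.csv"),
                manifest = file.path(config$out_dir, "manifest.yaml"))
  write_theta(fit$theta_final, paths$theta, mode = config$mode)
  utils::write.csv(data.frame(iter = seq_along(fit$loglik_per_iter),
                              loglik = fit$loglik_per_iter),
                   paths$em_trace, row.names = FALSE)
  utils::write.csv(data.frame(gdt = obs$times, mean = sp$mean,
                              var = t(apply(sp$cov, 3, diag))),
                   paths$smoothed, row.names = FALSE)
  utils::write.csv(fcs, paths$forecasts, row.names = FALSE)
  utils::write.csv(err, paths$error_summary, row.names = FALSE)
  cfg <- config
  cfg$out_dir <- NULL
  yaml::write_yaml(list(config = lapply(unclass(cfg), function(x)
    if (is.null(x)) NA else x),
    r_version = as.character(getRversion()),
    n_days = length(obs$times), n_observed = sum(obs$observed)),
    paths$manifest)
  invisible(list(theta = fit$theta_final, trace = fit, smoothed = sp,
                 forecasts = fcs, errors = err, paths = paths))
}

# internal: tiny --flag value parser for the CLI
parse_cli_args <- function(args) {
  if (length(args) == 0) return(list(cmd = NULL, opts = list()))
  cmd <- args[1]
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value")
    opts[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  list(cmd = cmd, opts = opts)
}

cli_usage <- function() {
  paste(
    "usage: cropdbn <command> [--flag value ...]",
    "commands:",
    "  simulate  --out FILE [--profile env1|env2|env3] [--mode M]",
    "            [--seed N] [--missing-rate R] [--n-days N]",
    "  fit       --data FILE --mode M --out THETA.json",
    "            [--max-iter N] [--rel-tol X] [--freeze C]",
    "  predict   --data FILE --theta THETA.json --q N --out FILE",
    "  benchmark --data FILE --mode M --out FILE",
    "  evaluate  --data FILE --mode M --q N --out DIR [--seed N]",
    sep = "\n")
}

#' Command-line interface
#'
#' Subcommands `simulate`, `fit`, `predict`, `benchmark` and `evaluate` over
#' the package's pipeline; intended to be called from a thin Rscript wrapper
#' (see `inst/cli/cropdbn.R`). Returns an exit code instead of quitting so it
#' can be tested in-process.
#'
#' @param args character vector of arguments (default: the command line).
#' @return Integer exit code: 0 on success, 1 on usage errors or failures
#'   (with a message on stderr).
#' @export
cropdbn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg) {
    message(msg)
    message(cli_usage())
    1L
  }
  pa <- tryCatch(parse_cli_args(args), error = function(e)
    conditionMessage(e))
  if (is.character(pa)) return(fail(pa))
  if (is.null(pa$cmd)) return(fail("no command given"))
  o <- pa$opts
  num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
  res <- tryCatch({
    switch(pa$cmd,
      simulate = {
        if (is.null(o$out)) stop("simulate: --out is required")
        mode <- if (is.null(o$mode)) "reciprocal_lai" else o$mode
        prof <- env_profile(if (is.null(o$profile)) "env1" else o$profile,
                            n_days = num(o$n_days, 64))
        sc <- generate_growth_scenario(scenario_config(
          profile = prof, mode = mode,
          missing_rate = num(o$missing_rate),
          seed = num(o$seed, 1)))
        write_series(sc$controls, sc$obs, o$out, mode = mode,
                     temp_c = sc$env$temp_c,
                     irradiance_mj = sc$env$irradiance_mj)
        message("wrote ", o$out)
        0L
      },
      fit = {
        if (is.null(o$data) || is.null(o$mode) || is.null(o$out))
          stop("fit: --data, --mode and --out are required")
        d <- read_series(o$data, o$mode)
        th0 <- build_initial_theta(d$obs, d$controls, mode = o$mode)
        fit <- fit_em(th0, d$controls, d$obs,
                      max_iter = num(o$max_iter, 100),
                      rel_tol = num(o$rel_tol, 1e-3),
                      freeze = if (is.null(o$freeze)) character() else
                        strsplit(o$freeze, ",")[[1]])
        write_theta(fit$theta_final, o$out, mode = o$mode)
        message("EM: ", fit$n_iter, " iteration(s), loglik ",
                format(fit$loglik_per_iter[fit$n_iter]), "; wrote ", o$out)
        0L
      },
      predict = {
        if (is.null(o$data) || is.null(o$theta) || is.null(o$out))
          stop("predict: --data, --theta and --out are required")
        q <- num(o$q, 21)
        if (q < 1) stop("predict: --q must be >= 1")
        td <- read_theta(o$theta)
        d <- read_series(o$data, td$mode)
        sp <- kalman_smooth(td$theta, d$controls, d$obs)
        last <- length(d$obs$times)
        fc <- forecast(td$theta, sp$mean[last, ], sp$cov[, , last],
                       d$controls$u[last, ], q)
        ind <- if (td$mode == "reciprocal_lai" && all(fc$y_mean > 0))
          reciprocal_backtransform(fc)$indicator_point else fc$y_mean
        utils::write.csv(data.frame(
          origin_T = d$obs$times[last], q = seq_len(q),
          y_mean = fc$y_mean, y_sd = sqrt(fc$y_var),
          indicator_point = ind), o$out, row.names = FALSE)
        message("wrote ", o$out)
        0L
      },
      benchmark = {
        if (is.null(o$data) || is.null(o$mode) || is.null(o$out))
          stop("benchmark: --data, --mode and --out are required")
        d <- read_series(o$data, o$mode)
        cg <- cumulative_gdd(d$controls$u[, 1])
        y_ind <- to_indicator_domain(d$obs$y, o$mode)
        obs_ind <- observation_series(d$obs$times, y_ind, d$obs$observed)
        if (o$mode == "reciprocal_lai") {
          carm <- carmassi_lai(cg)
          lrm_pred <- predict_lrm(fit_lrm_lai(obs_ind, cg), cg)
        } else {
          irr <- d$controls$u[, 2]
          carm <- baille_et(carmassi_lai(cg), irr)
          lrm_pred <- predict_lrm(fit_lrm_et(obs_ind, cg, irr), cg, irr)
        }
        utils::write.csv(data.frame(gdt = d$obs$times, carmassi = carm,
                                    lrm = lrm_pred), o$out, row.names = FALSE)
        message("wrote ", o$out)
        0L
      },
      evaluate = {
        if (is.null(o$data) || is.null(o$mode) || is.null(o$out))
          stop("evaluate: --data, --mode and --out are required")
        cfg <- run_config(mode = o$mode, q = num(o$q, 21),
                          seed = num(o$seed, 1), data_path = o$data,
                          out_dir = o$out)
        run_pipeline(cfg)
        message("artifacts in ", o$out)
        0L
      },
      stop("unknown command '", pa$cmd, "'"))
  }, error = function(e) conditionMessage(e))
  if (is.character(res)) return(fail(res))
  res
}
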