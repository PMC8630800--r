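#' Read and resolve a run configuration
#'
#' Configurations are YAML files with blocks `grid` (tau1: n, dt; tw:
#' explicit vector or preset name; omega3: start, step, n; omega_rf),
#' `truth`/`model` (flat key-value parameter sets with units in key names,
#' see [params_to_config()]), `snr`, `complex`, `seed`, `bounds`, `fit`
#' (any [fit_options()] field), and `cls` settings.  Unset fields fall back
#' to the water-regime defaults.
#'
#' @param path YAML file path, or a list already in config form.
#' @return Resolved config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  structure(cfg, class = "run_config")
}

config_grid <- function(cfg) {
  g <- cfg$grid
  if (is.null(g)) return(grid_mescn_h2o())
  tw <- g$tw
  if (is.character(tw) && tw == "experiment47") tw <- tw_axis_experiment()
  if (is.null(tw)) tw <- grid_mescn_h2o()$tw_axis
  axes_grid(
    tau1_axis = seq(0, by = g$tau1_dt_ps %||% 0.25,
                    length.out = g$tau1_n %||% 16),
    tw_axis = tw,
    omega3_axis = seq(g$omega3_start_cm1 %||% 2110,
                      by = g$omega3_step_cm1 %||% 1.5,
                      length.out = g$omega3_n %||% 64),
    omega_rf = g$omega_rf_cm1 %||% 2110)
}

#' Simulate a dataset from a run configuration and write it to disk
#'
#' @param config A `run_config` (or path, or list).
#' @param out Output directory for the dataset container.
#' @return The dataset, invisibly; the container is written to `out`.
#' @export
cmd_simulate <- function(config, out) {
  cfg <- read_run_config(config)
  truth <- if (!is.null(cfg$truth)) config_to_params(cfg$truth)
           else params_mescn_h2o()
  grid <- config_grid(cfg)
  snr <- cfg$snr
  if (is.null(snr)) {
    warning("cmd_simulate: no 'snr' field; generating a noiseless dataset")
    snr <- Inf
  }
  ds <- simulate_dataset(truth, grid, snr = snr,
                         complex_fid = isTRUE(cfg$complex),
                         seed = cfg$seed)
  write_dataset(ds, out)
  invisible(ds)
}

config_bounds <- function(cfg, p0) {
  if (!is.null(cfg$bounds)) {
    lo <- unlist(cfg$bounds$lo)[names(p0)]
    hi <- unlist(cfg$bounds$hi)[names(p0)]
    rbind(lo, hi)
  } else {
    b <- default_bounds_two_kubo()
    b[, names(p0), drop = FALSE]
  }
}

#' Fit a dataset from a run configuration and write a report
#'
#' Runs the Gauss-Newton fit with the configured model, writes
#' `report.json` (parameters, confidence intervals, VIF table, status,
#' resolved config), `traces.csv` (per-iteration cost and SIGN, restart
#' events), `residual.csv` (the residual cube in long format) and
#' `linear_absorption.csv` (the linear spectrum predicted from the fitted
#' parameters) into `out`.
#'
#' @param config A `run_config` (or path, or list).
#' @param dataset_path Dataset container directory (from [cmd_simulate()]).
#' @param out Output directory.
#' @return The `fit_result`, invisibly.
#' @export
cmd_fit <- function(config, dataset_path, out) {
  cfg <- read_run_config(config)
  if (!dir.exists(dataset_path))
    stop("cmd_fit: dataset not found: ", dataset_path)
  ds <- read_dataset(dataset_path)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n_kubo <- cfg$model$n_kubo %||% length(ds$provenance$truth$kubo) %||% 2
  nm <- param_names(n_kubo, phase = isTRUE(cfg$model$phase))
  p0 <- if (!is.null(cfg$model$p0)) unlist(cfg$model$p0)[nm] else NULL
  opt_args <- cfg$fit %||% list()
  options <- do.call(fit_options, opt_args)
  bounds <- config_bounds(cfg, setNames(numeric(length(nm)), nm))
  colnames(bounds) <- nm
  if (is.null(p0)) p0 <- random_restart(bounds)
  res <- fit_spectrum(ds, p0, bounds, options = options)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # traces
  tr <- data.frame(iteration = seq_along(res$state$cost_trace),
                   cost = res$state$cost_trace,
                   sign = res$state$sign_trace)
  write.csv(tr, file.path(out, "traces.csv"), row.names = FALSE)
  # residual cube
  model_vals <- model_spectrum(res$params_hat, ds$grid)
  resid <- Re(ds$values) - Re(model_vals)
  d <- dim(resid)
  idx <- expand.grid(i1 = seq_len(d[1]), i2 = seq_len(d[2]),
                     i3 = seq_len(d[3]))
  write.csv(data.frame(idx, residual = as.vector(resid)),
            file.path(out, "residual.csv"), row.names = FALSE)
  # predicted linear absorption
  om <- seq(res$params_hat$omega01 - 40, res$params_hat$omega01 + 40, by = 0.5)
  write.csv(data.frame(omega_cm1 = om,
                       absorbance = linear_absorption(res$params_hat, om)),
            file.path(out, "linear_absorption.csv"), row.names = FALSE)
  report <- list(
    status = res$status,
    converged = res$status == "converged",
    cost = res$cost,
    n_restarts = res$n_restarts,
    n_evals = res$n_evals,
    parameters = as.list(res$p_hat),
    ci95 = as.list(res$ci95),
    vif = as.list(res$vif),
    restart_log = res$state$restart_log,
    config = unclass(cfg))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}

#' CLS analysis from a run configuration
#'
#' Runs the CLS pipeline; when an absorption spectrum file (two-column
#' ASCII: wavenumber, absorbance) is configured and exists, includes the
#' amplitude step with standard and modified covariance side by side;
#' otherwise reports the CLS decay only, with a warning.
#'
#' @param config A `run_config` (or path, or list).
#' @param dataset_path Dataset container directory.
#' @param out Output directory.
#' @return The `cls_result`, invisibly.
#' @export
cmd_cls <- function(config, dataset_path, out) {
  cfg <- read_run_config(config)
  ds <- read_dataset(dataset_path)
  absorption <- NULL
  if (!is.null(cfg$cls$absorption_file)) {
    if (file.exists(cfg$cls$absorption_file)) {
      ab <- read.table(cfg$cls$absorption_file, header = FALSE,
                       col.names = c("omega", "absorbance"))
      absorption <- ab
    } else {
      warning("cmd_cls: absorption file missing; reporting CLS decay only")
    }
  }
  res <- cls_pipeline(ds, n_exp = cfg$cls$n_exp %||% 2,
                      absorption = absorption,
                      inv_t_lt = cfg$cls$inv_t_lt_ps1 %||% 0,
                      upper_fraction = cfg$cls$upper_fraction %||% 0.8,
                      modified = !is.null(absorption))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(tw_ps = res$decay$tw_axis,
                       cls = res$decay$cls_values),
            file.path(out, "cls_decay.csv"), row.names = FALSE)
  rep <- list(taus_ps = res$decay_fit$taus,
              amplitudes = res$decay_fit$amplitudes,
              identifiable = res$decay_fit$identifiable,
              config = unclass(cfg))
  if (!is.null(res$absorption_fit)) {
    af <- res$absorption_fit
    std_sd <- sqrt(pmax(diag(af$vcov), 0))
    rep$absorption_step <- list(
      inv_t_hom_ps1 = af$inv_t_hom, delta_sq_cm2 = af$delta_sq,
      scale = af$scale, offset = af$offset,
      ci95_standard = as.list(1.959964 * std_sd))
    if (!is.null(res$modified_vcov)) {
      mod_sd <- sqrt(pmax(diag(res$modified_vcov), 0))
      rep$absorption_step$ci95_modified <- as.list(1.959964 * mod_sd)
    }
  }
  jsonlite::write_json(rep, file.path(out, "cls_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}

#' Variance-inflation-factor comparison of fitting strategies
#'
#' Computes the VIF tables for the three standard scenarios at a given
#' parameter set: (A) naively fitting all dephasing parameters (with scaling
#' and offset) to the linear absorption spectrum, (B) the CLS-style
#' absorption fit with the Kubo times held fixed, and (C) full model fitting
#' to the 2D waiting-time series.  The hierarchy of their maxima
#' (A >> B >> C) quantifies how much better conditioned model fitting is.
#'
#' @param params True/fitted [lineshape_params()].
#' @param grid An [axes_grid()] for the model-fitting scenario.
#' @param upper_fraction Absorption window (default 0.8).
#' @return List of `vif_report`s: `naive`, `cls_constrained`,
#'   `model_fitting`, plus the absorption axis used.
#' @export
vif_scenarios <- function(params, grid, upper_fraction = 0.8) {
  om <- seq(params$omega01 - 40, params$omega01 + 40, by = 1)
  ab <- linear_absorption(params, om)
  keep <- ab >= (1 - upper_fraction) * max(ab)
  ok <- om[keep]
  nk <- length(params$kubo)
  taus <- vapply(params$kubo, `[[`, numeric(1), "tau")
  dsqs <- vapply(params$kubo, `[[`, numeric(1), "delta_sq")
  abs_model <- function(p, free_taus) {
    kubo <- lapply(seq_len(nk), function(i) {
      tt <- if (free_taus) p[[paste0("tau", i)]] else taus[i]
      kubo_component(max(p[[paste0("dsq", i)]], 0), max(tt, 1e-3))
    })
    pp <- lineshape_params(a01 = 1, a12 = 1, omega01 = params$omega01,
                           anh = params$anh, inv_t_lt = params$inv_t_lt,
                           inv_t_hom = max(p[["inv_t_hom"]],
                                           params$inv_t_lt / 2 * 1.001),
                           kubo = kubo)
    p[["scale"]] * linear_absorption(pp, ok) + p[["offset"]]
  }
  p_naive <- c(scale = 1, inv_t_hom = params$inv_t_hom,
               setNames(as.vector(rbind(taus, dsqs)),
                        as.vector(rbind(paste0("tau", 1:nk),
                                        paste0("dsq", 1:nk)))),
               offset = 0)
  J_naive <- jacobian_fd(function(p) abs_model(p, TRUE), p_naive)
  p_cons <- c(scale = 1, inv_t_hom = params$inv_t_hom,
              setNames(dsqs, paste0("dsq", 1:nk)), offset = 0)
  J_cons <- jacobian_fd(function(p) abs_model(p, FALSE), p_cons)
  pvec <- params_to_vector(params)
  model_fn <- function(p)
    flatten_spectrum(model_spectrum(vector_to_params(p), grid), FALSE)
  J_model <- jacobian_fd(model_fn, pvec)
  list(naive = vif(J_naive), cls_constrained = vif(J_cons),
       model_fitting = vif(J_model), omega_axis = ok)
}

#' Dephasing-parameter names of an n-component model
#'
#' The dephasing block: per-component correlation times and squared
#' amplitudes, plus the inverse homogeneous lifetime.  Everything else
#' (amplitudes, frequencies, anharmonicity, beta, vibrational lifetime) is
#' nondephasing.
#'
#' @param n_kubo Number of Kubo components.
#' @return Character vector.
#' @export
dephasing_names <- function(n_kubo) {
  c(as.vector(rbind(paste0("tau", seq_len(n_kubo)),
                    paste0("dsq", seq_len(n_kubo)))), "inv_t_hom")
}
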