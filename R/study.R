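#' Monte-Carlo simulation study: model fitting versus the CLS method
#'
#' Runs the package's central benchmarking experiment: `n_trials`
#' independent noise realizations of the two-Kubo waiting-time series at a
#' given SNR, each fitted from a random in-bounds start with the
#' Gauss-Newton engine, and (for the first `n_cls` trials) analyzed in
#' parallel with the CLS reference pipeline (asymmetric-Lorentzian
#' centerlines, biexponential decay fit including `tw = 0`, and the
#' amplitude step on the noiseless simulated absorption spectrum, upper
#' 80 percent).
#'
#' @param n_trials Number of fitted noise realizations.
#' @param n_cls Number of trials also analyzed with the CLS pipeline
#'   (`<= n_trials`).
#' @param seed Base seed; trial `i` uses `seed * 1000 + i`.
#' @param truth True parameters (default [params_mescn_h2o()]).
#' @param grid Sampling grid (default [grid_mescn_h2o()]).
#' @param snr Signal-to-noise ratio (default 600).
#' @param bounds Fitting bounds (default [default_bounds_two_kubo()]).
#' @param options Engine options.
#' @param progress Print one line per trial?
#' @return A list of class `simulation_study` with per-trial matrices:
#'   `fit_est`, `fit_ci95` (dephasing columns), `fit_status`, `fit_cost`,
#'   `n_data`, `cls_est`, plus `truth_vec` and `dephasing` (column names).
#' @export
simulation_study <- function(n_trials = 100, n_cls = 50, seed = 1,
                             truth = params_mescn_h2o(),
                             grid = grid_mescn_h2o(), snr = 600,
                             bounds = default_bounds_two_kubo(truth),
                             options = fit_options(),
                             progress = FALSE) {
  stopifnot(n_cls <= n_trials)
  n_kubo <- length(truth$kubo)
  dn <- dephasing_names(n_kubo)
  pv <- params_to_vector(truth)
  om <- seq(truth$omega01 - 40, truth$omega01 + 40, by = 1)
  ab <- linear_absorption(truth, om)
  fit_est <- matrix(NA_real_, n_trials, length(pv),
                    dimnames = list(NULL, names(pv)))
  fit_ci <- matrix(NA_real_, n_trials, length(pv),
                   dimnames = list(NULL, names(pv)))
  cls_est <- matrix(NA_real_, n_cls, length(dn),
                    dimnames = list(NULL, dn))
  status <- character(n_trials)
  cost <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(seed * 1000 + i)
    ds <- simulate_dataset(truth, grid, snr = snr)
    res <- fit_spectrum(ds, random_restart(bounds), bounds,
                        options = options)
    fit_est[i, ] <- res$p_hat
    if (!is.null(res$ci95)) fit_ci[i, ] <- res$ci95
    status[i] <- res$status
    cost[i] <- res$cost
    if (i <= n_cls) {
      cl <- tryCatch(
        cls_pipeline(ds, n_exp = n_kubo,
                     absorption = list(omega = om, absorbance = ab),
                     inv_t_lt = truth$inv_t_lt),
        error = function(e) NULL)
      if (!is.null(cl) && isTRUE(cl$decay_fit$identifiable) &&
          !is.null(cl$absorption_fit)) {
        f <- cl$decay_fit; a <- cl$absorption_fit
        est <- c(f$taus[1], a$delta_sq[1])
        if (n_kubo > 1) for (k in 2:n_kubo)
          est <- c(est, f$taus[k], a$delta_sq[k])
        cls_est[i, ] <- c(est, a$inv_t_hom)
      }
    }
    if (progress)
      message(sprintf("trial %3d: %s cost %.4g", i, status[i], cost[i]))
  }
  structure(list(fit_est = fit_est, fit_ci95 = fit_ci,
                 fit_status = status, fit_cost = cost,
                 n_data = length(grid$tau1_axis) * length(grid$tw_axis) *
                   length(grid$omega3_axis),
                 cls_est = cls_est, truth_vec = pv, dephasing = dn),
            class = "simulation_study")
}

#' Summary metrics of a simulation study
#'
#' Computes, over the dephasing parameters: the per-parameter fraction of
#' trials whose 95 percent confidence interval contains the truth
#' (`coverage`), the ratio of across-trial standard deviations CLS/model
#' for each Kubo time constant (`precision_ratio`), and the average
#' absolute relative deviation of the CLS estimates from truth in percent
#' (`cls_bias_pct`, per parameter and overall mean).
#'
#' @param study A `simulation_study`.
#' @return A list with `coverage`, `coverage_mean`, `precision_ratio`,
#'   `precision_ratio_min`, `cls_bias_pct`, `cls_bias_mean_pct`,
#'   `n_converged`.
#' @export
study_metrics <- function(study) {
  dn <- study$dephasing
  pv <- study$truth_vec
  inside <- abs(sweep(study$fit_est[, dn, drop = FALSE], 2, pv[dn])) <=
    study$fit_ci95[, dn, drop = FALSE]
  coverage <- colMeans(inside, na.rm = TRUE)
  tau_names <- dn[grepl("^tau", dn)]
  ok <- stats::complete.cases(study$cls_est)
  sd_cls <- apply(study$cls_est[ok, , drop = FALSE], 2, sd)
  n_fit_cls <- nrow(study$cls_est)
  sd_fit <- apply(study$fit_est[seq_len(n_fit_cls)[ok], dn, drop = FALSE],
                  2, sd)
  ratio <- sd_cls[tau_names] / sd_fit[tau_names]
  rel <- abs(sweep(study$cls_est[ok, , drop = FALSE], 2, pv[dn], "/") - 1)
  bias <- colMeans(rel) * 100
  list(coverage = coverage, coverage_mean = mean(coverage),
       precision_ratio = ratio, precision_ratio_min = min(ratio),
       cls_bias_pct = bias, cls_bias_mean_pct = mean(bias),
       n_converged = sum(study$fit_status == "converged"),
       n_cls_ok = sum(ok))
}

#' Model-fitting VIFs at the true parameters on the full grid
#'
#' Central-difference Jacobian of the flattened real-mode model at `truth`
#' on the full sampling grid with uniform weights, column-normalized; the
#' VIFs are split into the nondephasing block (amplitudes, center
#' frequency, calibration offset, anharmonicity, beta, inverse vibrational
#' lifetime) and the dephasing block (Kubo times and amplitudes, inverse
#' homogeneous lifetime).
#'
#' @param truth A [lineshape_params()] object.
#' @param grid An [axes_grid()] object.
#' @return A list with `vif` (full table), `max_nondephasing`,
#'   `max_dephasing`.
#' @export
model_vif_profile <- function(truth = params_mescn_h2o(),
                              grid = grid_mescn_h2o()) {
  pv <- params_to_vector(truth)
  model_fn <- function(p)
    as.vector(model_spectrum_real(vector_to_params(p), grid))
  J <- jacobian_fd(model_fn, pv)
  v <- vif(J)$vif
  dn <- dephasing_names(length(truth$kubo))
  list(vif = v,
       max_nondephasing = max(v[setdiff(names(pv), dn)]),
       max_dephasing = max(v[dn]))
}
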