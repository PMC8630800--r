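#' Absorptive 2D spectrum on a pump-frequency axis
#'
#' Transforms the measurement-domain values at one waiting time from the
#' pump coherence delay `tau1` to a pump frequency axis by an explicit
#' discrete Fourier evaluation (fine-grid, chirp-z style), taking the real
#' part.  The `tau1 = 0` point is half-weighted.  Because the measured data
#' contain both rephasing and nonrephasing pathways, the real part at
#' positive rotating-frame offsets is the absorptive spectrum.
#'
#' @param values_tw Real matrix `(tau1 x omega3)` of measurement-domain
#'   values at one waiting time.
#' @param grid An [axes_grid()] object.
#' @param omega1_axis Pump frequencies (cm^-1) at which to evaluate.
#' @return Real matrix `(omega1 x omega3)`.
#' @export
absorptive_spectrum2d <- function(values_tw, grid, omega1_axis) {
  tau1 <- grid$tau1_axis
  w <- rep(1, length(tau1)); w[1] <- 0.5
  ph <- outer(tau1, (omega1_axis - grid$omega_rf) * TWO_PI_C,
              function(t, o) -o * t)
  W1 <- exp(1i * ph) * w # n1 x n_omega1
  Re(t(W1) %*% values_tw)
}

#' Peak position of a probe-axis slice by an asymmetric Lorentzian fit
#'
#' Fits `A / (1 + ((x - x0)/gam)^2) + m x + c` to the slice and returns the
#' interior extremum of the fitted function (found numerically, not the max
#' bin).  Slices without an interior extremum of the right sign, or whose
#' fit fails, are rejected (`NA`).
#'
#' @param slice Intensity values along the probe axis.
#' @param axis Probe frequencies (cm^-1), same length.
#' @return Peak position (cm^-1), or `NA_real_` if rejected.
#' @export
slice_peak <- function(slice, axis) {
  stopifnot(length(slice) == length(axis))
  if (length(slice) < 6) return(NA_real_)
  i0 <- which.max(slice)
  a0 <- max(slice) - min(slice)
  if (a0 <= 0) return(NA_real_)
  half <- min(slice) + a0 / 2
  above <- which(slice >= half)
  g0 <- max(diff(range(axis[above])) / 2, diff(axis)[1])
  df <- data.frame(x = axis, y = slice)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + ((x - x0) / gam)^2) + m * x + c0,
                      data = df,
                      start = list(A = a0, x0 = axis[i0], gam = g0,
                                   m = 0, c0 = min(slice)),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  cf <- as.list(coef(fit))
  f <- function(x) cf$A / (1 + ((x - cf$x0) / cf$gam)^2) + cf$m * x + cf$c0
  opt <- optimize(f, range(axis), maximum = TRUE)
  span <- diff(range(axis))
  if (opt$maximum - min(axis) < 1e-3 * span ||
      max(axis) - opt$maximum < 1e-3 * span) return(NA_real_) # edge: reject
  opt$maximum
}

# Probe-axis analysis window around the 0-1 peak: +/- 1.5 apparent FWHM,
# floored above the midpoint to the (negative) 1-2 band.
probe_window <- function(spec2d, omega3) {
  imax <- which(spec2d == max(spec2d), arr.ind = TRUE)[1, ]
  ridge <- spec2d[imax[1], ]
  peak_pos <- omega3[imax[2]]
  half <- max(ridge) / 2
  above <- range(omega3[ridge >= half])
  fwhm <- max(diff(above), 2 * diff(omega3)[1])
  lo <- peak_pos - 1.5 * fwhm
  if (min(spec2d) < -0.05 * max(spec2d)) {
    imin <- which(spec2d == min(spec2d), arr.ind = TRUE)[1, ]
    esa_pos <- omega3[imin[2]]
    if (esa_pos < peak_pos) lo <- max(lo, (peak_pos + esa_pos) / 2)
  }
  c(lo, peak_pos + 1.5 * fwhm)
}

#' Centerline of an absorptive 2D spectrum
#'
#' For every pump frequency whose slice maximum reaches at least
#' `pump_frac` of the global maximum, fits the probe-axis slice within the
#' analysis window (+/- 1.5 apparent FWHM of the 0-1 band, floored above the
#' midpoint to the 1-2 band) with [slice_peak()].
#'
#' @param spec2d Real matrix `(omega1 x omega3)`.
#' @param omega1_axis,omega3_axis Axes (cm^-1).
#' @param pump_frac Pump-window threshold (default 0.5).
#' @return A list of class `centerline`: `pump_points`, `peak_positions`
#'   (rejected slices dropped), `n_rejected`, `window`.
#' @export
centerline <- function(spec2d, omega1_axis, omega3_axis, pump_frac = 0.5) {
  win <- probe_window(spec2d, omega3_axis)
  keep3 <- omega3_axis >= win[1] & omega3_axis <= win[2]
  gmax <- max(spec2d)
  slice_max <- apply(spec2d[, keep3, drop = FALSE], 1, max)
  rows <- which(slice_max >= pump_frac * gmax)
  peaks <- vapply(rows, function(r)
    slice_peak(spec2d[r, keep3], omega3_axis[keep3]), numeric(1))
  ok <- !is.na(peaks)
  structure(list(pump_points = omega1_axis[rows[ok]],
                 peak_positions = peaks[ok],
                 n_rejected = sum(!ok), window = win),
            class = "centerline")
}

#' Centerline slope of an absorptive 2D spectrum
#'
#' Unweighted linear regression of the probe-axis peak positions against
#' pump frequency.  A separable (uncorrelated) line shape gives 0; a fully
#' correlated diagonal ridge gives 1.
#'
#' @inheritParams centerline
#' @param min_points Minimum accepted centerline points (default 5).
#' @return Scalar slope.
#' @export
centerline_slope <- function(spec2d, omega1_axis, omega3_axis,
                             pump_frac = 0.5, min_points = 5) {
  cl <- centerline(spec2d, omega1_axis, omega3_axis, pump_frac)
  if (length(cl$pump_points) < min_points)
    stop("centerline_slope: fewer than ", min_points,
         " accepted centerline points")
  unname(coef(lm(cl$peak_positions ~ cl$pump_points))[2])
}

#' CLS decay of a waiting-time series
#'
#' Computes the centerline slope at every waiting time of a dataset.
#'
#' @param dataset A `spectral_dataset` (real-mode values are used; complex
#'   datasets use their real part).
#' @param omega1_axis Pump axis; default spans +/- 15 cm^-1 around the
#'   probe-axis global maximum at 0.5 cm^-1 steps.
#' @param pump_frac Pump-window threshold.
#' @return A list of class `cls_decay`: `tw_axis`, `cls_values`,
#'   `centerlines`.
#' @export
cls_decay <- function(dataset, omega1_axis = NULL, pump_frac = 0.5) {
  grid <- dataset$grid
  vals <- Re(dataset$values)
  if (is.null(omega1_axis)) {
    ta <- vals[1, 1, ]
    center <- grid$omega3_axis[which.max(ta)]
    omega1_axis <- seq(center - 15, center + 15, by = 0.5)
  }
  ntw <- length(grid$tw_axis)
  cls <- numeric(ntw)
  cl_list <- vector("list", ntw)
  for (b in seq_len(ntw)) {
    s2 <- absorptive_spectrum2d(vals[, b, ], grid, omega1_axis)
    cl_list[[b]] <- centerline(s2, omega1_axis, grid$omega3_axis, pump_frac)
    cls[b] <- centerline_slope(s2, omega1_axis, grid$omega3_axis, pump_frac)
  }
  structure(list(tw_axis = grid$tw_axis, cls_values = cls,
                 centerlines = cl_list),
            class = "cls_decay")
}

#' Fit a (bi)exponential model to a CLS decay
#'
#' Unweighted least-squares fit of `sum_i a_i exp(-tw / tau_i)`
#' (plus an optional static offset for quasi-static components), including
#' all waiting-time points.  Multi-start over a grid of time-constant pairs
#' guards against poor starting values.  A flat decay (relative spread below
#' `1e-3`) returns the static-offset branch with non-identifiable time
#' constants flagged.
#'
#' @param tw_axis Waiting times (ps).
#' @param cls_values CLS values.
#' @param n_exp Number of exponentials (1 or 2).
#' @param offset Include a constant offset?
#' @return A list of class `cls_decay_fit`: `amplitudes`, `taus` (sorted
#'   ascending), `offset`, `vcov` (full), `tau_vcov`, `identifiable`.
#' @export
fit_cls_decay <- function(tw_axis, cls_values, n_exp = 2, offset = FALSE) {
  stopifnot(n_exp %in% c(1, 2),
            length(tw_axis) >= 2 * n_exp + 1)
  spread <- diff(range(cls_values))
  if (spread < 1e-3 * max(abs(cls_values))) {
    return(structure(list(amplitudes = rep(NA_real_, n_exp),
                          taus = rep(NA_real_, n_exp),
                          offset = mean(cls_values), vcov = NULL,
                          tau_vcov = NULL, identifiable = FALSE),
                     class = "cls_decay_fit"))
  }
  df <- data.frame(t = tw_axis, y = cls_values)
  span <- max(tw_axis[tw_axis > 0])
  tau_grid <- exp(seq(log(max(min(diff(tw_axis)), 0.05)), log(span),
                      length.out = 5))
  best <- NULL
  try_fit <- function(form, start) {
    tryCatch({
      f <- minpack.lm::nlsLM(form, data = df, start = start,
                             lower = rep(1e-4, length(start)),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      list(fit = f, ssr = sum(residuals(f)^2))
    }, error = function(e) NULL)
  }
  if (n_exp == 1) {
    form <- if (offset) y ~ a1 * exp(-t / tau1) + c0 else y ~ a1 * exp(-t / tau1)
    for (tg in tau_grid) {
      st <- list(a1 = max(cls_values), tau1 = tg)
      if (offset) st$c0 <- min(cls_values)
      cand <- try_fit(form, st)
      if (!is.null(cand) && (is.null(best) || cand$ssr < best$ssr)) best <- cand
    }
  } else {
    form <- if (offset)
      y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c0
    else y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
    for (t1 in tau_grid) for (t2 in tau_grid) {
      if (t2 <= 2 * t1) next
      st <- list(a1 = spread / 2, tau1 = t1, a2 = spread / 2, tau2 = t2)
      if (offset) st$c0 <- min(cls_values)
      cand <- try_fit(form, st)
      if (!is.null(cand) && (is.null(best) || cand$ssr < best$ssr)) best <- cand
    }
  }
  if (is.null(best)) stop("fit_cls_decay: no exponential fit converged")
  cf <- coef(best$fit)
  V <- tryCatch(vcov(best$fit), error = function(e) NULL)
  tau_names <- paste0("tau", seq_len(n_exp))
  amp_names <- paste0("a", seq_len(n_exp))
  ord <- order(cf[tau_names])
  taus <- unname(cf[tau_names][ord])
  amps <- unname(cf[amp_names][ord])
  tau_vcov <- if (!is.null(V)) {
    tv <- V[tau_names, tau_names, drop = FALSE][ord, ord, drop = FALSE]
    dimnames(tv) <- list(tau_names, tau_names)
    tv
  }
  structure(list(amplitudes = amps, taus = taus,
                 offset = if (offset) unname(cf["c0"]) else 0,
                 vcov = V, tau_vcov = tau_vcov, identifiable = TRUE,
                 fit = best$fit),
            class = "cls_decay_fit")
}

#' Linear-absorption amplitude step of the CLS method
#'
#' Fits `scale * A(omega; inv_t_hom, Delta^2) + offset` to the upper part of
#' a linear absorption spectrum, holding the Kubo decay times fixed (from
#' the CLS decay fit) and, for multi-component models, holding the relative
#' Kubo amplitude fractions at the CLS component amplitude fractions.  Free
#' parameters: `inv_t_hom`, the total squared Kubo amplitude, the scaling,
#' and the offset.
#'
#' @param omega Absorption frequency axis (cm^-1).
#' @param absorbance Absorbance values.
#' @param taus_fixed Kubo correlation times (ps), held constant.
#' @param fractions Relative amplitude fractions (summing to 1); default
#'   equal split.
#' @param inv_t_lt Inverse vibrational lifetime (ps^-1), assumed known.
#' @param omega01 Center frequency; default the axis value at maximum.
#' @param upper_fraction Fit points with
#'   `absorbance >= (1 - upper_fraction) * max` (default 0.8).
#' @param p0 Optional named start (`inv_t_hom`, `dsq_tot`, `scale`,
#'   `offset`).
#' @param options [fit_options()] for the underlying Gauss-Newton fit.
#' @return A list of class `absorption_step_fit`: `p_hat`, `inv_t_hom`,
#'   `delta_sq` (per component), `scale`, `offset`, `vcov` (standard),
#'   `result` (full engine output), `omega_kept`.
#' @export
fit_linear_absorption_cls <- function(omega, absorbance, taus_fixed,
                                      fractions = NULL,
                                      inv_t_lt = 0, omega01 = NULL,
                                      upper_fraction = 0.8, p0 = NULL,
                                      options = fit_options(max_iters = 80)) {
  stopifnot(upper_fraction > 0, upper_fraction <= 1)
  if (max(absorbance) <= 0) stop("fit_linear_absorption_cls: empty spectrum")
  nk <- length(taus_fixed)
  if (is.null(fractions)) fractions <- rep(1 / nk, nk)
  fractions <- fractions / sum(fractions)
  keep <- absorbance >= (1 - upper_fraction) * max(absorbance)
  if (sum(keep) < 6) stop("fit_linear_absorption_cls: empty fit window")
  ok <- omega[keep]; ak <- absorbance[keep]
  if (is.null(omega01)) omega01 <- omega[which.max(absorbance)]
  ilt <- max(inv_t_lt, 1e-6)
  model_fn <- function(p) {
    kubo <- lapply(seq_len(nk), function(i)
      kubo_component(max(p[["dsq_tot"]], 0) * fractions[i], taus_fixed[i]))
    pp <- lineshape_params(a01 = 1, a12 = 1, omega01 = omega01, anh = 25,
                           inv_t_lt = ilt,
                           inv_t_hom = max(p[["inv_t_hom"]], ilt / 2 * 1.001),
                           kubo = kubo)
    p[["scale"]] * linear_absorption(pp, ok) + p[["offset"]]
  }
  if (is.null(p0))
    p0 <- c(inv_t_hom = 0.3, dsq_tot = 15, scale = max(ak), offset = 0)
  bounds <- rbind(c(inv_t_hom = max(ilt / 2 * 1.01, 1e-3), dsq_tot = 0.01,
                    scale = 1e-3 * max(ak), offset = -max(ak)),
                  c(inv_t_hom = 5, dsq_tot = 200,
                    scale = 10 * max(ak), offset = max(ak)))
  res <- fit_ls(ak, model_fn, p0, bounds, weights = 1, options = options)
  p <- res$p_hat
  structure(list(p_hat = p,
                 inv_t_hom = unname(p["inv_t_hom"]),
                 delta_sq = unname(p["dsq_tot"]) * fractions,
                 scale = unname(p["scale"]), offset = unname(p["offset"]),
                 vcov = res$vcov, result = res, omega_kept = ok,
                 taus_fixed = taus_fixed, fractions = fractions,
                 inv_t_lt = inv_t_lt, omega01 = omega01,
                 upper_fraction = upper_fraction),
            class = "absorption_step_fit")
}

#' Sensitivity of the absorption-step parameters to the fixed Kubo times
#'
#' Central finite differences of the constrained absorption fit with
#' respect to each fixed correlation time (1 percent steps): column j is
#' `d p_hat / d tau_j`.
#'
#' @param step_fit An `absorption_step_fit`.
#' @param omega,absorbance The fitted spectrum (full axis).
#' @param rel_step Relative perturbation of each tau (default 0.01).
#' @return Matrix `(n_params x n_taus)`.
#' @export
absorption_step_sensitivity <- function(step_fit, omega, absorbance,
                                        rel_step = 0.01) {
  taus <- step_fit$taus_fixed
  refit <- function(tt) {
    f <- fit_linear_absorption_cls(omega, absorbance, tt,
                                   fractions = step_fit$fractions,
                                   inv_t_lt = step_fit$inv_t_lt,
                                   omega01 = step_fit$omega01,
                                   upper_fraction = step_fit$upper_fraction,
                                   p0 = step_fit$p_hat)
    f$p_hat
  }
  S <- matrix(0, length(step_fit$p_hat), length(taus),
              dimnames = list(names(step_fit$p_hat),
                              paste0("tau", seq_along(taus))))
  for (j in seq_along(taus)) {
    h <- rel_step * taus[j]
    tp <- taus; tp[j] <- taus[j] + h
    tm <- taus; tm[j] <- taus[j] - h
    S[, j] <- (refit(tp) - refit(tm)) / (2 * h)
  }
  S
}

#' Modified covariance propagating Kubo-time uncertainty
#'
#' The standard covariance of the absorption-step fit treats the fixed Kubo
#' times as exactly known.  The modified covariance adds the first-order
#' propagated contribution of their uncertainty:
#' `V' = V_standard + S V_tau S^T`, where `S` is the sensitivity of the fit
#' parameters to the fixed times.  `V'` is never smaller than `V_standard`.
#'
#' @param standard_vcov Standard covariance of the absorption-step fit.
#' @param dfit_dtau Sensitivity matrix `S` (see
#'   [absorption_step_sensitivity()]).
#' @param tau_vcov Covariance of the Kubo time constants (PSD).
#' @return Modified covariance matrix.
#' @export
modified_covariance <- function(standard_vcov, dfit_dtau, tau_vcov) {
  tau_vcov <- as.matrix(tau_vcov)
  ev <- eigen(tau_vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("modified_covariance: tau_vcov is not positive semi-definite")
  standard_vcov + dfit_dtau %*% tau_vcov %*% t(dfit_dtau)
}

#' Full CLS analysis of a waiting-time series
#'
#' Runs the complete reference pipeline: centerlines and CLS at every
#' waiting time, a (bi)exponential decay fit including `tw = 0`, and --
#' when a linear absorption spectrum is supplied -- the amplitude step
#' holding the CLS decay times fixed, with standard and (optionally)
#' modified covariance.
#'
#' @param dataset A `spectral_dataset`.
#' @param n_exp Number of exponentials in the decay fit.
#' @param absorption Optional list/data.frame with `omega` and `absorbance`.
#' @param inv_t_lt Inverse vibrational lifetime assumed in the absorption
#'   step.
#' @param upper_fraction Absorption-step fit window (default 0.8).
#' @param modified Also compute the modified covariance (requires the
#'   sensitivity refits; default FALSE)?
#' @param pump_frac Pump-window threshold for the centerlines.
#' @return A list of class `cls_result`.
#' @export
cls_pipeline <- function(dataset, n_exp = 2, absorption = NULL,
                         inv_t_lt = 0, upper_fraction = 0.8,
                         modified = FALSE, pump_frac = 0.5) {
  dec <- cls_decay(dataset, pump_frac = pump_frac)
  fit <- fit_cls_decay(dec$tw_axis, dec$cls_values, n_exp = n_exp)
  out <- list(decay = dec, decay_fit = fit, absorption_fit = NULL,
              modified_vcov = NULL)
  if (!is.null(absorption) && isTRUE(fit$identifiable)) {
    fr <- fit$amplitudes / sum(fit$amplitudes)
    af <- fit_linear_absorption_cls(absorption$omega, absorption$absorbance,
                                    taus_fixed = fit$taus, fractions = fr,
                                    inv_t_lt = inv_t_lt,
                                    upper_fraction = upper_fraction)
    out$absorption_fit <- af
    if (modified && !is.null(fit$tau_vcov) && !is.null(af$vcov)) {
      S <- absorption_step_sensitivity(af, absorption$omega,
                                       absorption$absorbance)
      out$modified_vcov <- modified_covariance(af$vcov, S, fit$tau_vcov)
      out$sensitivity <- S
    }
  }
  class(out) <- "cls_result"
  out
}

#' @export
print.cls_result <- function(x, ...) {
  f <- x$decay_fit
  cat("CLS analysis\n")
  if (isTRUE(f$identifiable)) {
    for (i in seq_along(f$taus))
      cat(sprintf("  component %d: a = %.4g, tau = %.4g ps\n",
                  i, f$amplitudes[i], f$taus[i]))
  } else {
    cat("  decay flat: static offset", format(f$offset), "\n")
  }
  if (!is.null(x$absorption_fit)) {
    af <- x$absorption_fit
    cat(sprintf("  absorption step: inv_t_hom = %.4g ps-1, delta_sq = %s cm-2\n",
                af$inv_t_hom, paste(signif(af$delta_sq, 4), collapse = ", ")))
  }
  invisible(x)
}
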