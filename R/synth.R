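#' Simulate a noisy 2D IR waiting-time series at a defined SNR
#'
#' Evaluates the three-level Kubo forward model, adds i.i.d. Gaussian noise
#' to both quadratures of the free-induction decay, and transforms along the
#' probe axis.  The noise standard deviation is
#' `sigma = peak(|transient absorption at tw = 0|) / snr` -- signal defined
#' as the 0-1 peak magnitude of the zero-waiting-time transient absorption.
#' Because the probe-axis transform is unitary, the realized noise in the
#' fitted `(tau1, tw, omega3)` domain has the same standard deviation, so
#' the realized peak-signal-to-noise ratio of the dataset equals `snr`.
#'
#' @param truth A [lineshape_params()] object (recorded as provenance).
#' @param grid An [axes_grid()] object.
#' @param snr Signal-to-noise ratio (`> 0`); `Inf` for a noiseless dataset.
#' @param complex_fid Keep both quadratures (complex-valued detection) or
#'   only the real part (real-valued detection)?
#' @param seed Optional integer; when given, `set.seed(seed)` is called and
#'   the seed is recorded in the provenance.
#' @return A list of class `spectral_dataset`: `values` (real or complex
#'   array over `(tau1, tw, omega3)`), `grid`, `weights` (uniform),
#'   `complex_fid`, `provenance` (truth, snr, sigma, seed).
#' @export
simulate_dataset <- function(truth, grid, snr = Inf, complex_fid = FALSE,
                             seed = NULL) {
  stopifnot(snr > 0)
  if (!is.null(seed)) set.seed(seed)
  fid <- third_order_fid(truth, grid)
  sigma <- 0
  if (is.finite(snr)) {
    ta <- transient_absorption(truth, grid, grid$tw_axis[1])
    sigma <- max(abs(ta)) / snr
    noise <- array(complex(real = rnorm(length(fid), 0, sigma),
                           imaginary = rnorm(length(fid), 0, sigma)),
                   dim = dim(fid))
    fid <- fid + noise
  }
  spec <- spectrum_from_fid_cpp(fid, grid$t3_axis, grid$omega3_axis,
                                grid$omega_rf)
  values <- if (complex_fid) spec else Re(spec)
  structure(list(values = values, grid = grid,
                 weights = array(1, dim = dim(values)),
                 complex_fid = complex_fid,
                 provenance = list(truth = truth, snr = snr, sigma = sigma,
                                   seed = seed)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("2D IR waiting-time series: %d tau1 x %d tw x %d omega3 (%s)\n",
              d[1], d[2], d[3],
              if (isTRUE(x$complex_fid)) "complex" else "real"))
  if (!is.null(x$provenance$snr))
    cat(sprintf("  synthetic, SNR %s, noise sigma %.4g\n",
                format(x$provenance$snr), x$provenance$sigma))
  invisible(x)
}

#' Waiting-time undersampling mask
#'
#' Keeps every `k`-th waiting-time point on each side of a pivot (counting
#' outward from the point nearest the pivot, which is always kept), always
#' keeps the final point, and drops points before `exclude_before` (the
#' pulse-overlap window).
#'
#' @param tw_axis Waiting times (ps).
#' @param k Stride (`>= 1`).
#' @param pivot Pivot time (ps), default 1.
#' @param exclude_before Exclusion window (ps), default 0.3: points with
#'   `tw < exclude_before` are never kept.
#' @return A list of class `sampling_mask`: logical `kept_tw`, `k`,
#'   `pivot`, `exclude_before`, `n_kept`.
#' @export
make_mask <- function(tw_axis, k, pivot = 1, exclude_before = 0.3) {
  stopifnot(k >= 1, k == round(k))
  eligible <- tw_axis >= exclude_before
  if (sum(eligible) < 2) stop("make_mask: fewer than 2 eligible points")
  idx <- which(eligible)
  ip <- idx[which.min(abs(tw_axis[idx] - pivot))] # nearest-to-pivot, kept
  keep <- rep(FALSE, length(tw_axis))
  keep[ip] <- TRUE
  left <- idx[idx < ip]
  right <- idx[idx > ip]
  if (length(left) >= k) # every kth point outward (towards earlier times)
    keep[rev(left)[seq(k, length(left), by = k)]] <- TRUE
  if (length(right) >= k)
    keep[right[seq(k, length(right), by = k)]] <- TRUE
  keep[idx[length(idx)]] <- TRUE # final point always kept
  if (sum(keep) < 2) stop("make_mask: mask keeps fewer than 2 points")
  structure(list(kept_tw = keep, k = k, pivot = pivot,
                 exclude_before = exclude_before, n_kept = sum(keep)),
            class = "sampling_mask")
}

#' Apply a sampling mask to a dataset
#'
#' @param dataset A `spectral_dataset`.
#' @param mask A `sampling_mask` from [make_mask()].
#' @return A `spectral_dataset` restricted to the kept waiting times.
#' @export
apply_mask <- function(dataset, mask) {
  keep <- mask$kept_tw
  stopifnot(length(keep) == length(dataset$grid$tw_axis))
  g <- dataset$grid
  grid <- axes_grid(g$tau1_axis, g$tw_axis[keep], g$omega3_axis, g$omega_rf)
  out <- dataset
  out$values <- dataset$values[, keep, , drop = FALSE]
  out$weights <- dataset$weights[, keep, , drop = FALSE]
  out$grid <- grid
  out
}

#' Interpolate a nonuniform probe axis onto a uniform one
#'
#' Cubic-spline interpolation per `(tau1, tw)` slice (FMM end conditions,
#' which reproduce cubic polynomials exactly).  Extrapolation is refused.
#'
#' @param values Array over `(tau1, tw, omega3)` or a vector.
#' @param nonuniform_axis Strictly monotonic probe axis of the input.
#' @param target_uniform_axis Target axis, contained in the input's span.
#' @return Values on the target axis (same leading dimensions).
#' @export
interpolate_probe_axis <- function(values, nonuniform_axis,
                                   target_uniform_axis) {
  d <- diff(nonuniform_axis)
  if (all(d < 0)) { # tolerate decreasing axes by reversing
    nonuniform_axis <- rev(nonuniform_axis)
    values <- if (is.array(values))
      values[, , rev(seq_along(nonuniform_axis)), drop = FALSE]
    else rev(values)
    d <- diff(nonuniform_axis)
  }
  if (any(d <= 0))
    stop("interpolate_probe_axis: axis must be strictly monotonic")
  if (min(target_uniform_axis) < min(nonuniform_axis) - 1e-9 ||
      max(target_uniform_axis) > max(nonuniform_axis) + 1e-9)
    stop("interpolate_probe_axis: target axis requests extrapolation")
  interp1 <- function(y)
    splinefun(nonuniform_axis, y, method = "fmm")(target_uniform_axis)
  if (!is.array(values)) return(interp1(values))
  dims <- dim(values)
  out <- array(if (is.complex(values)) complex(1) else 0,
               dim = c(dims[1], dims[2], length(target_uniform_axis)))
  for (a in seq_len(dims[1])) for (b in seq_len(dims[2])) {
    y <- values[a, b, ]
    out[a, b, ] <- if (is.complex(y))
      complex(real = interp1(Re(y)), imaginary = interp1(Im(y)))
    else interp1(y)
  }
  out
}

#' Invert an apodization window applied in the time domain
#'
#' Divides by the window where it is safely away from zero; points where
#' `|window| < floor_frac * max(|window|)` are zeroed and flagged so their
#' weights can be zeroed too (never divide by a near-zero gain).  If the
#' original filter half-scaled the DC (first) component, the DC point is
#' restored by the factor 2.
#'
#' @param values_timedomain Vector or array whose last dimension is time.
#' @param window Per-point gains (length of the time axis).
#' @param dc_half_scaled Did the original filter apply 1/2 to the DC term?
#' @param floor_frac Relative floor (default 0.05).
#' @return List with `values` (deapodized), `kept` (logical per time point:
#'   FALSE where the window was below the floor and data were zeroed).
#' @export
invert_apodization <- function(values_timedomain, window,
                               dc_half_scaled = FALSE, floor_frac = 0.05) {
  nt <- if (is.array(values_timedomain))
    dim(values_timedomain)[length(dim(values_timedomain))]
  else length(values_timedomain)
  if (length(window) != nt)
    stop("invert_apodization: window length must match the time axis")
  if (max(abs(window)) == 0)
    stop("invert_apodization: entire window below the floor")
  floor_val <- floor_frac * max(abs(window))
  kept <- abs(window) >= floor_val
  inv <- ifelse(kept, 1 / window, 0)
  if (dc_half_scaled) inv[1] <- inv[1] * 2
  if (is.array(values_timedomain)) {
    out <- sweep(values_timedomain, length(dim(values_timedomain)), inv, "*")
  } else {
    out <- values_timedomain * inv
  }
  list(values = out, kept = kept)
}

# ---- on-disk container ---------------------------------------------------

#' Write / read a spectral dataset as a plain-text container
#'
#' The container is a directory holding `manifest.json` (axes, units,
#' provenance, flags) and `values.csv` (long format: indices plus real and,
#' when complex, imaginary parts, and weights).  Entirely text-based so
#' datasets travel through version control and survive any platform.
#'
#' @param dataset A `spectral_dataset`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$grid
  prov <- dataset$provenance
  manifest <- list(
    format = "kubofit-dataset-v1",
    complex_fid = isTRUE(dataset$complex_fid),
    tau1_axis_ps = g$tau1_axis, tw_axis_ps = g$tw_axis,
    omega3_axis_cm1 = g$omega3_axis, omega_rf_cm1 = g$omega_rf,
    provenance = list(
      snr = if (!is.null(prov$snr)) unbox_num(prov$snr) else NULL,
      sigma = prov$sigma, seed = prov$seed,
      truth = if (!is.null(prov$truth)) params_to_config(prov$truth)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  d <- dim(dataset$values)
  idx <- expand.grid(i1 = seq_len(d[1]), i2 = seq_len(d[2]),
                     i3 = seq_len(d[3]))
  df <- data.frame(idx, re = as.vector(Re(dataset$values)))
  if (isTRUE(dataset$complex_fid)) df$im <- as.vector(Im(dataset$values))
  df$weight <- as.vector(dataset$weights)
  write.csv(df, file.path(path, "values.csv"), row.names = FALSE)
  invisible(path)
}

unbox_num <- function(x) if (is.infinite(x)) "Inf" else x

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- axes_grid(manifest$tau1_axis_ps, manifest$tw_axis_ps,
                 manifest$omega3_axis_cm1, manifest$omega_rf_cm1)
  df <- read.csv(file.path(path, "values.csv"))
  d <- c(length(g$tau1_axis), length(g$tw_axis), length(g$omega3_axis))
  ord <- order(df$i3, df$i2, df$i1)
  df <- df[ord, ]
  cplx <- isTRUE(manifest$complex_fid)
  values <- if (cplx)
    array(complex(real = df$re, imaginary = df$im), dim = d)
  else array(df$re, dim = d)
  weights <- if ("weight" %in% names(df)) array(df$weight, dim = d)
             else array(1, dim = d)
  prov <- manifest$provenance
  truth <- if (!is.null(prov$truth) && length(prov$truth) > 0)
    config_to_params(as.list(prov$truth)) else NULL
  snr <- prov$snr
  if (identical(snr, "Inf")) snr <- Inf
  structure(list(values = values, grid = g, weights = weights,
                 complex_fid = cplx,
                 provenance = list(truth = truth, snr = snr,
                                   sigma = prov$sigma, seed = prov$seed)),
            class = "spectral_dataset")
}
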