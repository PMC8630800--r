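#' @useDynLib kubofit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef vcov qnorm runif rnorm sd optimize spline splinefun setNames residuals
#' @importFrom utils modifyList write.csv read.csv read.table
NULL

#' Speed of light in cm/ps
#'
#' Unit conversion constants.  Frequencies and frequency fluctuations are
#' stored in wavenumbers (cm^-1, cm^-2); times in picoseconds.  Conversion to
#' angular units inside the response functions uses `2*pi*c` with
#' `c = 0.0299792458` cm/ps.
#' @keywords internal
C_CM_PS <- 0.0299792458

#' @rdname C_CM_PS
#' @keywords internal
TWO_PI_C <- 2 * pi * C_CM_PS

#' Kubo component of a frequency-fluctuation correlation function
#'
#' One exponentially decaying term `delta_sq * exp(-t/tau)` of the FFCF,
#' with squared fluctuation amplitude `delta_sq` in cm^-2 and correlation
#' time `tau` in ps.
#'
#' @param delta_sq Squared fluctuation amplitude (cm^-2), `>= 0`.
#' @param tau Correlation time (ps), `> 0`.
#' @return A list of class `kubo_component`.
#' @export
kubo_component <- function(delta_sq, tau) {
  stopifnot(is.numeric(delta_sq), is.numeric(tau),
            length(delta_sq) == 1, length(tau) == 1)
  if (delta_sq < 0) stop("kubo_component: delta_sq must be >= 0")
  if (tau <= 0) stop("kubo_component: tau must be > 0")
  structure(list(delta_sq = delta_sq, tau = tau), class = "kubo_component")
}

#' Line-shape parameters of the three-level Kubo model
#'
#' The full parameter set of the forward model: peak amplitudes of the 0-1
#' and 1-2 transitions, 0-1 center frequency, a pump-axis calibration offset
#' (modeled on exactly one axis), the anharmonic shift, the scaling `beta` of
#' the 1-2 fluctuation amplitude relative to the 0-1, the inverse vibrational
#' lifetime and inverse homogeneous lifetime, a list of Kubo components, and
#' an optional zero-order phase.
#'
#' The physical bound `inv_t_hom > inv_t_lt / 2` is enforced: the homogeneous
#' dephasing rate contains the lifetime contribution `inv_t_lt / 2`, so it can
#' never fall below it.
#'
#' @param a01 0-1 peak amplitude (signal units).
#' @param a12 1-2 peak amplitude (signal units).
#' @param omega01 0-1 center frequency (cm^-1).
#' @param d_omega1 Pump-axis calibration offset (cm^-1).
#' @param anh Anharmonic shift (cm^-1); the 1-2 transition sits at
#'   `omega01 - anh`.
#' @param beta Unitless scaling of the 1-2 Kubo fluctuation amplitude
#'   (`Delta^2(1-2) = beta^2 Delta^2(0-1)`).
#' @param inv_t_lt Inverse vibrational lifetime (ps^-1), `> 0`.
#' @param inv_t_hom Inverse homogeneous lifetime (ps^-1),
#'   `> inv_t_lt / 2`.
#' @param kubo List of [kubo_component()] objects (possibly empty).
#' @param phi0 Zero-order phase (rad); default 0.
#' @param lt12_ratio Ratio `T_LT(1-2) / T_LT(0-1)`; the 1-2 coherence in the
#'   detection period acquires the extra lifetime-broadening rate
#'   `(inv_t_lt + inv_t_lt / lt12_ratio) / 2`.  Default 0.5 (harmonic
#'   scaling of the ladder relaxation rate).
#' @return A list of class `lineshape_params`.
#' @export
lineshape_params <- function(a01, a12, omega01, d_omega1 = 0, anh,
                             beta = 1, inv_t_lt, inv_t_hom,
                             kubo = list(), phi0 = 0, lt12_ratio = 0.5) {
  if (inv_t_lt <= 0) stop("lineshape_params: inv_t_lt must be > 0")
  if (inv_t_hom <= inv_t_lt / 2)
    stop("lineshape_params: physical bound violated: inv_t_hom must exceed inv_t_lt/2")
  if (lt12_ratio <= 0) stop("lineshape_params: lt12_ratio must be > 0")
  kubo <- lapply(kubo, function(k) {
    if (inherits(k, "kubo_component")) k else kubo_component(k[[1]], k[[2]])
  })
  structure(list(a01 = a01, a12 = a12, omega01 = omega01,
                 d_omega1 = d_omega1, anh = anh, beta = beta,
                 inv_t_lt = inv_t_lt, inv_t_hom = inv_t_hom,
                 kubo = kubo, phi0 = phi0, lt12_ratio = lt12_ratio),
            class = "lineshape_params")
}

#' @export
print.lineshape_params <- function(x, ...) {
  cat("Three-level Kubo line-shape parameters\n")
  cat(sprintf("  a01 = %.4g, a12 = %.4g, omega01 = %.4f cm-1\n",
              x$a01, x$a12, x$omega01))
  cat(sprintf("  d_omega1 = %.4g cm-1, anh = %.4f cm-1, beta = %.4g\n",
              x$d_omega1, x$anh, x$beta))
  cat(sprintf("  inv_t_lt = %.5g ps-1, inv_t_hom = %.5g ps-1, phi0 = %.3g rad\n",
              x$inv_t_lt, x$inv_t_hom, x$phi0))
  for (i in seq_along(x$kubo))
    cat(sprintf("  Kubo %d: delta_sq = %.4g cm-2, tau = %.4g ps\n",
                i, x$kubo[[i]]$delta_sq, x$kubo[[i]]$tau))
  invisible(x)
}

kubo_matrix <- function(params) {
  if (length(params$kubo) == 0) return(matrix(numeric(0), 0, 2))
  t(vapply(params$kubo, function(k) c(k$delta_sq, k$tau), numeric(2)))
}

#' Sampling axes of a 2D IR waiting-time series
#'
#' The measurement-domain axes: uniform pump coherence delays `tau1` (ps),
#' waiting times `tw` (ps, any spacing), and a uniform probe-frequency axis
#' `omega3` (cm^-1).  The rotating-frame frequency `omega_rf` fixes the
#' time-frequency convention of the probe-axis transform; the implied probe
#' time grid has spacing `1 / (N * d_omega3 * c)` so that the transform is a
#' (unitary) discrete Fourier transform.
#'
#' @param tau1_axis Strictly increasing, uniformly spaced pump delays (ps).
#' @param tw_axis Strictly increasing waiting times (ps).
#' @param omega3_axis Strictly increasing, uniformly spaced probe
#'   frequencies (cm^-1).
#' @param omega_rf Rotating-frame frequency (cm^-1).
#' @return A list of class `axes_grid` with the derived `t3_axis`.
#' @export
axes_grid <- function(tau1_axis, tw_axis, omega3_axis, omega_rf) {
  check_uniform <- function(x, nm) {
    if (length(x) < 2 || any(diff(x) <= 0))
      stop("axes_grid: ", nm, " must be strictly increasing")
    d <- diff(x)
    if (max(abs(d - d[1])) > 1e-9 * d[1])
      stop("axes_grid: ", nm, " must be uniformly spaced")
    d[1]
  }
  check_uniform(tau1_axis, "tau1_axis")
  if (any(diff(tw_axis) <= 0))
    stop("axes_grid: tw_axis must be strictly increasing")
  d3 <- check_uniform(omega3_axis, "omega3_axis")
  n3 <- length(omega3_axis)
  dt3 <- 1 / (n3 * d3 * C_CM_PS)
  structure(list(tau1_axis = tau1_axis, tw_axis = tw_axis,
                 omega3_axis = omega3_axis, omega_rf = omega_rf,
                 t3_axis = (seq_len(n3) - 1) * dt3,
                 unit_conv = TWO_PI_C),
            class = "axes_grid")
}

#' Documented simulation fixture: nitrile probe in water
#'
#' Two-Kubo parameter set representative of the C=N stretch of a small
#' thiocyanate probe (MeSCN) in water: a fast, partially motionally narrowed
#' component (tau ~ 0.4 ps) from hydrogen-bond fluctuations and a slower
#' structural component (tau ~ 3.6 ps), on top of homogeneous dephasing and
#' a several-picosecond vibrational lifetime.  These defaults define the
#' simulation-study conditions used throughout the tests.
#'
#' @return A [lineshape_params()] object.
#' @export
params_mescn_h2o <- function() {
  lineshape_params(a01 = 1.0, a12 = 1.1, omega01 = 2163.0, d_omega1 = 0.15,
                   anh = 25.5, beta = 1.1, inv_t_lt = 0.12, inv_t_hom = 0.42,
                   kubo = list(kubo_component(12, 0.4),
                               kubo_component(10, 3.6)))
}

#' Documented example parameter set: MeSCN in DMSO (one Kubo component)
#'
#' Reported one-Kubo fit of the C=N stretch of MeSCN in DMSO: a 3.57 ps
#' Kubo component of squared amplitude 14.8 cm^-2, homogeneous rate
#' 0.229 ps^-1 and a 72.5 ps vibrational lifetime.  Useful as a realistic
#' slow-modulation example.
#'
#' @return A [lineshape_params()] object.
#' @export
params_mescn_dmso <- function() {
  lineshape_params(a01 = 16.56, a12 = 18.73, omega01 = 2153.319,
                   d_omega1 = 0.137, anh = 25.483, beta = 1.138,
                   inv_t_lt = 0.01379, inv_t_hom = 0.229,
                   kubo = list(kubo_component(14.8, 3.57)))
}

#' Default desk-scale grid for the water-regime fixture
#'
#' 16 pump delays at 0.25 ps steps, 45 waiting times from 0 to 12 ps (dense
#' early to sample the fast Kubo component, sparser late), and 64 probe
#' frequencies at 1.5 cm^-1 spanning both the 0-1 and 1-2 bands.
#'
#' @return An [axes_grid()] object.
#' @export
grid_mescn_h2o <- function() {
  tw <- c(seq(0, 1, by = 0.1),
          seq(1.2, 3, by = 0.2),
          seq(3.25, 6, by = 0.25),
          seq(6.5, 12, by = 0.5))
  stopifnot(length(tw) == 45)
  axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 16),
            tw_axis = tw,
            omega3_axis = seq(2110, by = 1.5, length.out = 64),
            omega_rf = 2110)
}

#' Experiment-like 47-point waiting-time axis
#'
#' A 47-point waiting-time axis of the kind used for slow probes (long
#' vibrational lifetime): two points inside the pulse-overlap window
#' (0 and 0.2 ps), dense sampling up to 1 ps, and progressively coarser
#' sampling out to 24 ps.  Designed for use with [make_mask()] (pivot at
#' 1 ps, 0.3 ps exclusion).
#'
#' @return Numeric vector of 47 waiting times (ps).
#' @export
tw_axis_experiment <- function() {
  tw <- c(0, 0.2,
          c(0.3, 0.35, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
          seq(1.25, 3, by = 0.25),
          seq(3.5, 10, by = 0.5),
          seq(11, 24, by = 1))
  stopifnot(length(tw) == 47)
  tw
}

# ---- flat parameter-vector mapping used by the fitting wrappers ----------

#' Names of the flat fitting-parameter vector for an n-component model
#'
#' Order follows the conventional listing: amplitudes, center frequency,
#' calibration offset, anharmonicity, then per-component (tau_i, dsq_i),
#' then beta and the inverse lifetimes, optionally the zero-order phase.
#'
#' @param n_kubo Number of Kubo components.
#' @param phase Include the zero-order phase parameter `phi0`?
#' @return Character vector of parameter names.
#' @export
param_names <- function(n_kubo, phase = FALSE) {
  nm <- c("a01", "a12", "omega01", "d_omega1", "anh")
  if (n_kubo > 0)
    nm <- c(nm, as.vector(rbind(paste0("tau", seq_len(n_kubo)),
                                paste0("dsq", seq_len(n_kubo)))))
  nm <- c(nm, "beta", "inv_t_lt", "inv_t_hom")
  if (phase) nm <- c(nm, "phi0")
  nm
}

#' Convert a named parameter vector to a `lineshape_params` object
#'
#' @param p Named numeric vector using [param_names()] conventions.
#' @param lt12_ratio Passed through to [lineshape_params()].
#' @return A [lineshape_params()] object.
#' @export
vector_to_params <- function(p, lt12_ratio = 0.5) {
  nm <- names(p)
  taus <- sort(as.integer(sub("tau", "", nm[grepl("^tau[0-9]+$", nm)])))
  kubo <- lapply(taus, function(i)
    kubo_component(p[[paste0("dsq", i)]], p[[paste0("tau", i)]]))
  lineshape_params(a01 = p[["a01"]], a12 = p[["a12"]],
                   omega01 = p[["omega01"]], d_omega1 = p[["d_omega1"]],
                   anh = p[["anh"]], beta = p[["beta"]],
                   inv_t_lt = p[["inv_t_lt"]], inv_t_hom = p[["inv_t_hom"]],
                   kubo = kubo,
                   phi0 = if ("phi0" %in% nm) p[["phi0"]] else 0,
                   lt12_ratio = lt12_ratio)
}

#' Convert a `lineshape_params` object to a named vector
#'
#' @param params A [lineshape_params()] object.
#' @param phase Include `phi0`?
#' @return Named numeric vector.
#' @export
params_to_vector <- function(params, phase = FALSE) {
  n <- length(params$kubo)
  p <- c(a01 = params$a01, a12 = params$a12, omega01 = params$omega01,
         d_omega1 = params$d_omega1, anh = params$anh)
  for (i in seq_len(n)) {
    p[paste0("tau", i)] <- params$kubo[[i]]$tau
    p[paste0("dsq", i)] <- params$kubo[[i]]$delta_sq
  }
  p <- c(p, beta = params$beta, inv_t_lt = params$inv_t_lt,
         inv_t_hom = params$inv_t_hom)
  if (phase) p <- c(p, phi0 = params$phi0)
  p[param_names(n, phase)]
}

#' Serialize parameters to a flat key-value list with units in key names
#'
#' @param params A [lineshape_params()] object.
#' @return Named list suitable for `yaml::write_yaml()`.
#' @export
params_to_config <- function(params) {
  out <- list(a01_au = params$a01, a12_au = params$a12,
              omega01_cm1 = params$omega01, d_omega1_cm1 = params$d_omega1,
              anh_cm1 = params$anh, beta = params$beta,
              inv_t_lt_ps1 = params$inv_t_lt, inv_t_hom_ps1 = params$inv_t_hom,
              phi0_rad = params$phi0, lt12_ratio = params$lt12_ratio)
  for (i in seq_along(params$kubo)) {
    out[[paste0("kubo", i, "_delta_sq_cm2")]] <- params$kubo[[i]]$delta_sq
    out[[paste0("kubo", i, "_tau_ps")]] <- params$kubo[[i]]$tau
  }
  out
}

#' @rdname params_to_config
#' @param config Named list produced by [params_to_config()].
#' @export
config_to_params <- function(config) {
  i <- 1
  kubo <- list()
  while (!is.null(config[[paste0("kubo", i, "_tau_ps")]])) {
    kubo[[i]] <- kubo_component(config[[paste0("kubo", i, "_delta_sq_cm2")]],
                                config[[paste0("kubo", i, "_tau_ps")]])
    i <- i + 1
  }
  lineshape_params(a01 = config$a01_au, a12 = config$a12_au,
                   omega01 = config$omega01_cm1,
                   d_omega1 = config$d_omega1_cm1 %||% 0,
                   anh = config$anh_cm1, beta = config$beta %||% 1,
                   inv_t_lt = config$inv_t_lt_ps1,
                   inv_t_hom = config$inv_t_hom_ps1, kubo = kubo,
                   phi0 = config$phi0_rad %||% 0,
                   lt12_ratio = config$lt12_ratio %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
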