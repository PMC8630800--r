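#' Kubo line-shape function g(t)
#'
#' Double time integral of the frequency-fluctuation correlation function
#' `delta(t)/T_hom + sum_i Delta_i^2 exp(-t/tau_i)`:
#' \deqn{g(t) = t/T_{hom} + \sum_i \Delta_i^2 \tau_i^2
#'       [e^{-t/\tau_i} + t/\tau_i - 1]}
#' with `Delta_i^2` converted from cm^-2 to rad^2/ps^2 by `(2 pi c)^2`.
#' The delta-correlated term integrates to exactly `t * inv_t_hom`, making
#' `inv_t_hom` the Lorentzian half-width rate.
#'
#' @param t Time(s), ps, `>= 0`.
#' @param params A [lineshape_params()] object.
#' @return Numeric vector `g(t)` (unitless, real, `>= 0`).
#' @export
lineshape_g <- function(t, params) {
  if (any(t < 0)) stop("lineshape_g: t must be >= 0")
  g <- params$inv_t_hom * t
  for (k in params$kubo) {
    dsq <- k$delta_sq * TWO_PI_C^2
    g <- g + dsq * k$tau^2 * (exp(-t / k$tau) + t / k$tau - 1)
  }
  g
}

# Kubo-only part (no homogeneous term), used by the response assembly.
lineshape_g_kubo <- function(t, params) {
  g <- numeric(length(t))
  for (k in params$kubo) {
    dsq <- k$delta_sq * TWO_PI_C^2
    g <- g + dsq * k$tau^2 * (exp(-t / k$tau) + t / k$tau - 1)
  }
  g
}

# Extra dephasing rate of the 1-2 coherence in the detection period from
# lifetime broadening of the 1-2 transition: (inv_t_lt,01 + inv_t_lt,12)/2.
esa_rate_add <- function(params) {
  0.5 * (params$inv_t_lt + params$inv_t_lt / params$lt12_ratio)
}

#' Third-order free-induction decay of the three-level system
#'
#' Complex response over `(tau1, tw, t3)`: rephasing plus nonrephasing
#' ground-state-bleach/stimulated-emission pathways (weight `a01`, at
#' `omega01`) and excited-state absorption (weight `-a12`, at
#' `omega01 - anh`), with second-order-cumulant dephasing built from
#' [lineshape_g()], population decay `exp(-tw * inv_t_lt)` on all pathways,
#' lifetime broadening of the 1-2 coherence during `t3`, the pump-axis
#' calibration offset applied as a frequency shift during `tau1` only, and
#' a global zero-order phase.
#'
#' @param params A [lineshape_params()] object.
#' @param grid An [axes_grid()] object.
#' @return Complex array of dimension
#'   `(length(tau1_axis), length(tw_axis), length(t3_axis))`.
#' @export
third_order_fid <- function(params, grid) {
  stopifnot(inherits(params, "lineshape_params"), inherits(grid, "axes_grid"))
  fid_cube_cpp(grid$tau1_axis, grid$tw_axis, grid$t3_axis,
               params$a01, params$a12, params$omega01, params$d_omega1,
               params$anh, params$beta, params$inv_t_lt, params$inv_t_hom,
               params$phi0, esa_rate_add(params), kubo_matrix(params),
               grid$omega_rf)
}

#' Unitary probe-axis DFT matrix
#'
#' Matrix `W` such that `spectrum = fid %*% W` maps the probe time axis onto
#' `omega3_axis`.  The first time point is half-weighted (causal/DC
#' convention) and the `1/sqrt(N)` scaling makes the transform preserve the
#' standard deviation of white noise.  For a uniform `omega3_axis` matched to
#' the implied `t3` grid the matrix is proportional to a unitary DFT and is
#' exactly invertible.
#'
#' @param grid An [axes_grid()] object.
#' @return Complex `N x N` matrix.
#' @export
probe_dft_matrix <- function(grid) {
  probe_dft_matrix_cpp(grid$t3_axis, grid$omega3_axis, grid$omega_rf)
}

#' Model 2D IR spectrum in the measurement domain
#'
#' Discrete Fourier transform of [third_order_fid()] along `t3` only,
#' aligned to `grid$omega3_axis`.  Deterministic; exactly linear in the
#' amplitudes `a01` and `a12`.
#'
#' @param params A [lineshape_params()] object.
#' @param grid An [axes_grid()] object.
#' @return Complex array over `(tau1, tw, omega3)`.  The real part is the
#'   measured (absorptive-detection) signal.
#' @export
model_spectrum <- function(params, grid) {
  fid <- third_order_fid(params, grid)
  spectrum_from_fid_cpp(fid, grid$t3_axis, grid$omega3_axis, grid$omega_rf)
}

#' Real-part model spectrum (fast path for fitting)
#'
#' Identical to `Re(model_spectrum(params, grid))` but fused in compiled
#' code: the detection-domain real part is assembled with a single real
#' matrix product.  Used by the fitting wrappers, where only the measured
#' quadrature is needed.
#'
#' @inheritParams model_spectrum
#' @return Real array over `(tau1, tw, omega3)`.
#' @export
model_spectrum_real <- function(params, grid) {
  m <- spectrum_real_cpp(grid$tau1_axis, grid$tw_axis, grid$t3_axis,
                         params$a01, params$a12, params$omega01,
                         params$d_omega1, params$anh, params$beta,
                         params$inv_t_lt, params$inv_t_hom, params$phi0,
                         esa_rate_add(params), kubo_matrix(params),
                         grid$omega3_axis, grid$omega_rf)
  dim(m) <- c(length(grid$tau1_axis), length(grid$tw_axis),
              length(grid$omega3_axis))
  m
}

#' Linear absorption spectrum predicted by the line-shape parameters
#'
#' \deqn{A(\omega) \propto \mathrm{Re}\int_0^\infty
#'   e^{i(\omega-\omega_{01}) 2\pi c\, t}\; e^{-g(t) - t\,T_{LT}^{-1}/2}\,dt}
#' evaluated by direct quadrature on a fine time grid and normalized to unit
#' peak.
#'
#' @param params A [lineshape_params()] object.
#' @param omega_axis Probe frequencies (cm^-1).
#' @return Real vector, unit peak maximum.
#' @export
linear_absorption <- function(params, omega_axis) {
  stopifnot(inherits(params, "lineshape_params"))
  rate <- params$inv_t_hom + params$inv_t_lt / 2
  # choose t_max where the envelope has decayed to ~1e-14
  env <- function(t) lineshape_g(t, params) + t * params$inv_t_lt / 2
  # cap t_max: beyond ~2 ns the residual linewidth (< 0.003 cm^-1) is far
  # below any realistic grid resolution
  t_max <- 1
  while (env(t_max) < 32 && t_max < 2000) t_max <- t_max * 2
  dom_max <- max(abs(omega_axis - params$omega01)) + 1
  dt <- min(0.1 / (dom_max * TWO_PI_C), t_max / 2048)
  t <- seq(0, t_max, by = dt)
  decay <- exp(-env(t))
  w <- rep(1, length(t)); w[1] <- 0.5; w[length(t)] <- 0.5
  wd <- w * decay
  # evaluate in frequency chunks to bound the outer-product memory
  a <- numeric(length(omega_axis))
  idx <- split(seq_along(omega_axis),
               ceiling(seq_along(omega_axis) / 64))
  for (ii in idx) {
    ph <- outer((omega_axis[ii] - params$omega01) * TWO_PI_C, t)
    a[ii] <- as.vector(cos(ph) %*% wd) * dt
  }
  a / max(a)
}

#' Transient absorption spectrum at a waiting time
#'
#' The `tau1 = 0` slice of the real part of [model_spectrum()] at waiting
#' time `tw` -- the projection-slice equivalent of a spectrally integrated
#' pump.  Its zero-waiting-time 0-1 peak magnitude defines the signal in the
#' signal-to-noise ratio of [simulate_dataset()].
#'
#' @param params A [lineshape_params()] object.
#' @param grid An [axes_grid()] object whose `tau1_axis` contains 0.
#' @param tw Waiting time (ps); must lie on `grid$tw_axis`.
#' @return Real vector over `omega3`.
#' @export
transient_absorption <- function(params, grid, tw) {
  i1 <- which(abs(grid$tau1_axis) < 1e-12)
  if (length(i1) != 1) stop("transient_absorption: tau1 axis must contain 0")
  i2 <- which(abs(grid$tw_axis - tw) < 1e-9)
  if (length(i2) != 1) stop("transient_absorption: tw not on the grid")
  spec <- model_spectrum(params, grid)
  Re(spec[i1, i2, ])
}
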