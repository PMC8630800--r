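# Small grids and parameter sets shared across tests.

tiny_grid <- function(n1 = 4, n2 = 3, n3 = 16) {
  axes_grid(tau1_axis = seq(0, by = 0.25, length.out = n1),
            tw_axis = c(0, 1, 4)[seq_len(n2)],
            omega3_axis = seq(2110, by = 3, length.out = n3),
            omega_rf = 2110)
}

# reduced water-regime grid for fast engine tests
small_grid <- function() {
  axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 8),
            tw_axis = c(0, 0.3, 0.7, 1.2, 2, 3.2, 5, 8, 12),
            omega3_axis = seq(2110, by = 3, length.out = 32),
            omega_rf = 2110)
}

# full width at half maximum with linear interpolation of the crossings
fwhm_interp <- function(x, y) {
  y <- y / max(y)
  i <- which.max(y)
  left <- approx(y[1:i], x[1:i], xout = 0.5, ties = "ordered")$y
  right <- approx(rev(y[i:length(y)]), rev(x[i:length(x)]), xout = 0.5,
                  ties = "ordered")$y
  right - left
}

one_kubo_params <- function() {
  lineshape_params(a01 = 1, a12 = 1.05, omega01 = 2160, d_omega1 = 0.1,
                   anh = 25, beta = 1.05, inv_t_lt = 0.15, inv_t_hom = 0.4,
                   kubo = list(kubo_component(12, 2)))
}

one_kubo_bounds <- function() {
  nm <- param_names(1)
  lo <- c(a01 = 0.1, a12 = 0.1, omega01 = 2150, d_omega1 = -1, anh = 20,
          tau1 = 0.1, dsq1 = 1, beta = 0.5, inv_t_lt = 0.01,
          inv_t_hom = 0.05)
  hi <- c(a01 = 10, a12 = 10, omega01 = 2170, d_omega1 = 1, anh = 30,
          tau1 = 15, dsq1 = 60, beta = 2, inv_t_lt = 1, inv_t_hom = 2)
  rbind(lo[nm], hi[nm])
}
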