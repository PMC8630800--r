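# Independent slow-path oracles.  These deliberately avoid the package's
# lineshape_g / C++ response code: g is computed by brute-force 2-D
# quadrature of the FFCF double integral, and the third-order response is
# assembled term by term in plain R.

TWO_PI_C_ORACLE <- 2 * pi * 0.0299792458

# FFCF without the delta-correlated part (rad^2/ps^2)
oracle_ffcf <- function(u, kubo) {
  out <- 0
  for (k in kubo) out <- out + k$delta_sq * TWO_PI_C_ORACLE^2 * exp(-u / k$tau)
  out
}

# g(t) by nested trapezoidal quadrature of the FFCF double integral,
# plus the exact t/T_hom contribution of the delta-correlated term
oracle_g <- function(t, params, n_outer = 600, n_inner = 400) {
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    s <- seq(0, tt, length.out = n_outer + 1)
    inner <- vapply(s, function(ss) {
      if (ss == 0) return(0)
      u <- seq(0, ss, length.out = n_inner + 1)
      w <- rep(1, n_inner + 1); w[c(1, n_inner + 1)] <- 0.5
      sum(w * oracle_ffcf(u, params$kubo)) * ss / n_inner
    }, numeric(1))
    w <- rep(1, n_outer + 1); w[c(1, n_outer + 1)] <- 0.5
    params$inv_t_hom * tt + sum(w * inner) * tt / n_outer
  }, numeric(1))
}

# third-order FID assembled term by term from oracle_g (quadrature-based);
# same conventions as the package: GSB/SE at omega01 (weight a01), ESA at
# omega01 - anh (weight -a12), population decay on all pathways, beta
# scaling of the 1-2 Kubo fluctuations, ESA lifetime-broadening addition
oracle_fid <- function(params, grid, g_fun = NULL) {
  if (is.null(g_fun)) {
    # tabulate the quadrature g on the needed arguments once
    args <- sort(unique(round(c(
      outer(grid$tau1_axis, outer(grid$tw_axis, grid$t3_axis, "+"), "+"),
      outer(grid$tau1_axis, grid$tw_axis, "+"),
      outer(grid$tw_axis, grid$t3_axis, "+"),
      grid$tau1_axis, grid$tw_axis, grid$t3_axis, 0), 12)))
    gtab <- oracle_g(args, params)
    g_fun <- function(t) gtab[match(round(t, 12), args)]
  }
  gk_fun <- function(t) g_fun(t) - params$inv_t_hom * t # Kubo part only
  om1p <- (params$omega01 + params$d_omega1 - grid$omega_rf) * TWO_PI_C_ORACLE
  om01 <- (params$omega01 - grid$omega_rf) * TWO_PI_C_ORACLE
  om12 <- (params$omega01 - params$anh - grid$omega_rf) * TWO_PI_C_ORACLE
  esa_add <- 0.5 * (params$inv_t_lt + params$inv_t_lt / params$lt12_ratio)
  n1 <- length(grid$tau1_axis); n2 <- length(grid$tw_axis)
  n3 <- length(grid$t3_axis)
  out <- array(0i, dim = c(n1, n2, n3))
  for (a in seq_len(n1)) for (b in seq_len(n2)) for (cc in seq_len(n3)) {
    t1 <- grid$tau1_axis[a]; t2 <- grid$tw_axis[b]; t3 <- grid$t3_axis[cc]
    B <- gk_fun(t1 + t2 + t3) - gk_fun(t1 + t2) - gk_fun(t2 + t3) +
      gk_fun(t2)
    gh1 <- params$inv_t_hom * t1
    gh3 <- params$inv_t_hom * t3
    e01_r <- exp(-(gh1 + gh3 + gk_fun(t1) + gk_fun(t3) - B))
    e01_n <- exp(-(gh1 + gh3 + gk_fun(t1) + gk_fun(t3) + B))
    e12_r <- exp(-(gh1 + (params$inv_t_hom + esa_add) * t3 + gk_fun(t1) +
                     params$beta^2 * gk_fun(t3) - params$beta * B))
    e12_n <- exp(-(gh1 + (params$inv_t_hom + esa_add) * t3 + gk_fun(t1) +
                     params$beta^2 * gk_fun(t3) + params$beta * B))
    reph <- exp(1i * om1p * t1) *
      (params$a01 * exp(-1i * om01 * t3) * e01_r -
         params$a12 * exp(-1i * om12 * t3) * e12_r)
    nonr <- exp(-1i * om1p * t1) *
      (params$a01 * exp(-1i * om01 * t3) * e01_n -
         params$a12 * exp(-1i * om12 * t3) * e12_n)
    out[a, b, cc] <- exp(1i * params$phi0) * exp(-params$inv_t_lt * t2) *
      (reph + nonr)
  }
  out
}

# dense-sum discrete Fourier transform along t3 (independent of the
# package's DFT matrix code); same half-first-point and 1/sqrt(N) scaling
oracle_probe_dft <- function(fid, grid) {
  t3 <- grid$t3_axis; om <- grid$omega3_axis
  n3 <- length(t3)
  w <- rep(1, n3); w[1] <- 0.5
  d <- dim(fid)
  out <- array(0i, dim = c(d[1], d[2], length(om)))
  for (k in seq_along(om)) {
    ph <- exp(1i * (om[k] - grid$omega_rf) * TWO_PI_C_ORACLE * t3)
    for (a in seq_len(d[1])) for (b in seq_len(d[2]))
      out[a, b, k] <- sum(fid[a, b, ] * ph * w) / sqrt(n3)
  }
  out
}
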