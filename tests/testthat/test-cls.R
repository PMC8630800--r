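test_that("slice peak finding recovers symmetric and tilted Lorentzians", {
  axis <- seq(2140, 2180, by = 1.5)
  lor <- function(x, x0, g) 1 / (1 + ((x - x0) / g)^2)
  # symmetric case: exact center recovery
  expect_lt(abs(slice_peak(lor(axis, 2161.3, 5), axis) - 2161.3), 1.5e-3)
  # tilted case: the extremum shifts off the bin maximum; compare with a
  # dense numerical extremum of the generating function
  f <- function(x) lor(x, 2160, 5) + 0.004 * (x - 2160)
  dense <- seq(2140, 2180, by = 1e-3)
  true_peak <- dense[which.max(f(dense))]
  got <- slice_peak(f(axis), axis)
  expect_gt(true_peak, 2160) # tilt moves the peak up-frequency
  expect_lt(abs(got - true_peak), 0.01)
  # monotonic slice: rejected
  expect_true(is.na(slice_peak(seq(0, 1, length.out = 27), axis)))
})

test_that("centerline slope separates uncorrelated and correlated line shapes", {
  om1 <- seq(2150, 2170, by = 0.5)
  om3 <- seq(2140, 2180, by = 1)
  lor <- function(x, x0, g) 1 / (1 + ((x - x0) / g)^2)
  # separable product line shape: no pump-probe correlation
  sep <- outer(lor(om1, 2160, 4), lor(om3, 2160, 5))
  expect_lt(abs(centerline_slope(sep, om1, om3)), 0.01)
  # fully correlated diagonal ridge
  corr <- outer(om1, om3, function(a, b) lor(b, a, 4)) *
    lor(om1, 2160, 6)
  expect_equal(centerline_slope(corr, om1, om3), 1, tolerance = 0.02)
  expect_error(centerline_slope(sep[1:2, , drop = FALSE], om1[1:2], om3),
               "centerline points")
})

test_that("static limit: CLS at tw 0 approaches 1 as tau goes static", {
  # the echo ridge of a static component persists for ~1/inv_t_hom along
  # the pump delay, so the scan must cover several homogeneous lifetimes
  p <- lineshape_params(a01 = 1, a12 = 0, omega01 = 2160, anh = 25,
                        inv_t_lt = 0.01, inv_t_hom = 0.1,
                        kubo = list(kubo_component(36, 1e4)))
  g <- axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 128),
                 tw_axis = c(0, 0.5),
                 omega3_axis = seq(2130, by = 0.75, length.out = 80),
                 omega_rf = 2130)
  ds <- simulate_dataset(p, g, snr = Inf)
  om1 <- seq(2148, 2172, by = 0.4)
  s2 <- absorptive_spectrum2d(ds$values[, 1, ], g, om1)
  expect_equal(centerline_slope(s2, om1, g$omega3_axis), 1, tolerance = 0.02)
})

test_that("CLS decay is bounded, monotone, and matches a dense-grid oracle", {
  truth <- params_mescn_dmso() # slow modulation, one Kubo component
  g <- axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 16),
                 tw_axis = c(0, 0.5, 1, 1.5, 2, 3, 4, 5.5, 7, 9, 12, 15),
                 omega3_axis = seq(2105, by = 1.5, length.out = 64),
                 omega_rf = 2105)
  ds <- simulate_dataset(truth, g, snr = Inf)
  dec <- cls_decay(ds)
  expect_true(all(dec$cls_values > -1e-3 & dec$cls_values < 1 + 1e-3))
  expect_true(all(diff(dec$cls_values) < 1e-3))
  # dense-model oracle: same analysis on a finer probe axis and pump grid
  g_dense <- axes_grid(tau1_axis = seq(0, by = 0.125, length.out = 48),
                       tw_axis = g$tw_axis,
                       omega3_axis = seq(2105, by = 0.75, length.out = 128),
                       omega_rf = 2105)
  ds_dense <- simulate_dataset(truth, g_dense, snr = Inf)
  dec_dense <- cls_decay(ds_dense)
  # measurement-grid discretization shifts the CLS by a few percent at most
  expect_lt(max(abs(dec$cls_values - dec_dense$cls_values)), 0.04)
})

test_that("biexponential CLS decay fitting recovers exact inputs", {
  tw <- seq(0, 12, length.out = 45)
  y <- 0.3 * exp(-tw / 3.3)
  f1 <- fit_cls_decay(tw, y, n_exp = 1)
  expect_equal(f1$taus, 3.3, tolerance = 1e-8)
  expect_equal(f1$amplitudes, 0.3, tolerance = 1e-8)
  y2 <- 0.15 * exp(-tw / 0.5) + 0.2 * exp(-tw / 4)
  f2 <- fit_cls_decay(tw, y2, n_exp = 2)
  expect_equal(f2$taus, c(0.5, 4), tolerance = 1e-6)
  expect_equal(f2$amplitudes, c(0.15, 0.2), tolerance = 1e-6)
  expect_true(all(is.finite(diag(f2$tau_vcov))))
  # constant decay: static-offset branch, times not identifiable
  fc <- fit_cls_decay(tw, rep(0.25, 45), n_exp = 1)
  expect_false(fc$identifiable)
  expect_equal(fc$offset, 0.25)
  expect_true(is.na(fc$taus[1]))
})

test_that("CLS decay time tracks the FFCF correlation time in slow modulation", {
  truth <- params_mescn_dmso() # Delta tau 2 pi c ~ 2.6: slow modulation
  g <- axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 16),
                 tw_axis = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6.5, 8, 10, 12.5, 15),
                 omega3_axis = seq(2105, by = 1.5, length.out = 64),
                 omega_rf = 2105)
  ds <- simulate_dataset(truth, g, snr = Inf)
  dec <- cls_decay(ds)
  fit <- fit_cls_decay(dec$tw_axis, dec$cls_values, n_exp = 1)
  expect_equal(fit$taus, truth$kubo[[1]]$tau, tolerance = 0.10)
})

test_that("absorption amplitude step round-trips noiseless spectra", {
  truth <- params_mescn_h2o()
  om <- seq(truth$omega01 - 40, truth$omega01 + 40, by = 1)
  ab <- linear_absorption(truth, om)
  taus <- vapply(truth$kubo, `[[`, numeric(1), "tau")
  dsqs <- vapply(truth$kubo, `[[`, numeric(1), "delta_sq")
  af <- fit_linear_absorption_cls(om, ab, taus_fixed = taus,
                                  fractions = dsqs / sum(dsqs),
                                  inv_t_lt = truth$inv_t_lt,
                                  p0 = c(inv_t_hom = 0.5, dsq_tot = 25,
                                         scale = 1.2, offset = 0.01))
  expect_equal(af$inv_t_hom, truth$inv_t_hom, tolerance = 1e-4)
  expect_equal(sum(af$delta_sq), sum(dsqs), tolerance = 1e-4)
  expect_equal(af$scale, 1, tolerance = 1e-4)
  expect_equal(af$offset, 0, tolerance = 1e-5)
  expect_error(fit_linear_absorption_cls(om, rep(0, length(om)),
                                         taus_fixed = taus),
               "empty spectrum")
})

test_that("baseline distortion drifts the absorption-step parameters", {
  truth <- params_mescn_h2o()
  om <- seq(truth$omega01 - 40, truth$omega01 + 40, by = 1)
  ab <- linear_absorption(truth, om) +
    0.03 * (om - truth$omega01) / 40 + 0.02 # distorted baseline
  taus <- vapply(truth$kubo, `[[`, numeric(1), "tau")
  dsqs <- vapply(truth$kubo, `[[`, numeric(1), "delta_sq")
  ests <- vapply(c(0.9, 0.8, 0.7), function(uf) {
    af <- fit_linear_absorption_cls(om, ab, taus_fixed = taus,
                                    fractions = dsqs / sum(dsqs),
                                    inv_t_lt = truth$inv_t_lt,
                                    upper_fraction = uf)
    c(af$inv_t_hom, sum(af$delta_sq))
  }, numeric(2))
  # fit-window sensitivity: estimates move as the window shrinks
  expect_gt(max(ests[1, ]) - min(ests[1, ]), 1e-4)
  expect_gt(max(ests[2, ]) - min(ests[2, ]), 1e-3)
})

test_that("modified covariance adds the propagated Kubo-time uncertainty", {
  V <- diag(c(1e-4, 4e-4))
  S <- matrix(c(0.5, -1, 0.2, 0.3), 2, 2)
  expect_equal(modified_covariance(V, S, matrix(0, 2, 2)), V)
  Vt <- diag(c(0.01, 0.04))
  Vm <- modified_covariance(V, S, Vt)
  dd <- eigen(Vm - V, symmetric = TRUE)$values
  expect_true(all(dd > -1e-12)) # V' is never smaller than V
  expect_error(modified_covariance(V, S, matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("uncertain Kubo times inflate absorption-step variances dramatically", {
  truth <- params_mescn_h2o()
  om <- seq(truth$omega01 - 40, truth$omega01 + 40, by = 1)
  ab <- linear_absorption(truth, om)
  taus <- vapply(truth$kubo, `[[`, numeric(1), "tau")
  dsqs <- vapply(truth$kubo, `[[`, numeric(1), "delta_sq")
  af <- fit_linear_absorption_cls(om, ab, taus_fixed = taus,
                                  fractions = dsqs / sum(dsqs),
                                  inv_t_lt = truth$inv_t_lt,
                                  p0 = c(inv_t_hom = 0.5, dsq_tot = 25,
                                         scale = 1.2, offset = 0.01))
  S <- absorption_step_sensitivity(af, om, ab)
  tau_vcov <- diag((0.1 * taus)^2) # 10 percent time-constant uncertainty
  Vm <- modified_covariance(af$vcov, S, tau_vcov)
  # variances inflate by orders of magnitude relative to the certain-tau case
  expect_gt(min(diag(Vm) / pmax(diag(af$vcov), 1e-300)), 100)
})

test_that("modified covariance matches Monte-Carlo refits on a 1-parameter toy", {
  # toy: Gaussian of fixed width w; the free parameter is the amplitude.
  # With w uncertain, the amplitude variance inflates by S V_w S^T.
  x <- seq(-3, 3, by = 0.1)
  w0 <- 1.2
  model <- function(a, w) a * exp(-x^2 / (2 * w^2))
  d <- model(2, w0)
  fit_amp <- function(w) { # closed-form LS amplitude given width
    m <- model(1, w)
    sum(m * d) / sum(m * m)
  }
  h <- 0.01 * w0
  S <- (fit_amp(w0 + h) - fit_amp(w0 - h)) / (2 * h)
  sd_w <- 0.02 * w0 # small width uncertainty
  pred_var <- S^2 * sd_w^2 # V_standard = 0 (noiseless)
  set.seed(42)
  mc <- vapply(1:4000, function(i) fit_amp(w0 + rnorm(1, 0, sd_w)),
               numeric(1))
  expect_equal(var(mc), pred_var, tolerance = 0.2)
})

test_that("VIF hierarchy: naive >> CLS-constrained >> model fitting", {
  truth <- params_mescn_h2o()
  g <- axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 8),
                 tw_axis = c(0, 0.3, 0.8, 1.5, 2.5, 4, 6, 9, 12),
                 omega3_axis = seq(2110, by = 3, length.out = 32),
                 omega_rf = 2110)
  sc <- vif_scenarios(truth, g)
  deph_naive <- max(sc$naive$vif[c("inv_t_hom", "tau1", "dsq1",
                                   "tau2", "dsq2")])
  deph_cons <- max(sc$cls_constrained$vif[c("inv_t_hom", "dsq1", "dsq2")])
  deph_model <- max(sc$model_fitting$vif[dephasing_names(2)])
  expect_gt(deph_naive, 10 * deph_cons)
  expect_gt(deph_cons, 10 * deph_model)
})

test_that("degenerate Kubo pairs drive the VIFs into the huge-value regime", {
  truth <- params_mescn_h2o()
  pv <- params_to_vector(truth)
  pv["tau2"] <- pv["tau1"] * (1 + 1e-9) # tau1 ~ tau2: amplitudes collinear
  g <- axes_grid(tau1_axis = seq(0, by = 0.25, length.out = 8),
                 tw_axis = c(0, 0.5, 1.5, 3, 6, 10),
                 omega3_axis = seq(2110, by = 3, length.out = 32),
                 omega_rf = 2110)
  model_fn <- function(p)
    as.vector(model_spectrum_real(vector_to_params(p), g))
  J <- jacobian_fd(model_fn, pv)
  v <- vif(J)
  expect_true(v$condition_flag)
  expect_gt(max(v$vif[c("dsq1", "dsq2")]), 1e10)
})
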