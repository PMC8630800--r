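# kubofit

Least-squares fitting of two-dimensional infrared (2D IR) waiting-time
series to generalized Kubo line-shape models.

## What problem this solves, and for whom

2D IR spectroscopists usually quantify spectral diffusion with approximate
line-shape metrics — most commonly the centerline slope (CLS) — and then
recover absolute Kubo amplitudes and homogeneous dephasing by a second fit
to the linear absorption spectrum.  That two-step route depends on the
short-time approximation, on the availability and quality of a linear
spectrum, and on a severely ill-conditioned absorption fit whose error
bars silently omit the uncertainty of the fixed Kubo time constants.

`kubofit` instead fits a generalized Kubo line-shape model *directly* to
the measured waiting-time series in the measurement domain
$(\tau_1, T_w, \omega_3)$.  The frequency-fluctuation correlation function
(FFCF) is

$$\langle\delta\omega_{01}(t)\,\delta\omega_{01}(0)\rangle
  = \delta(t)\,T_\mathrm{hom}^{-1} + \sum_i \Delta_i^2\,e^{-t/\tau_i},$$

and the data model is the isotropic third-order response of a three-level
vibrational system (0–1 and anharmonically shifted 1–2 transitions) built
from the line-shape function $g(t)$ by the second-order cumulant
expansion, transformed along the probe axis only.  The package provides:

* a compiled forward model (response functions, 2D spectra, linear and
  transient absorption);
* a Gauss–Newton engine with central-difference Jacobians, Armijo
  backtracking, boundary correction, and a **scale-invariant gradient
  norm (SIGN)** stopping criterion,
  $\mathrm{SIGN}_i = \lVert\nabla C_i \odot \sigma_{p,i}\rVert/C_{i-1}$,
  which is invariant to the scaling of data, weights and problem size and
  doubles as a stall detector — stalls (boundaries, degenerate Kubo
  pairs, singular normal equations) are resolved by random restarts;
* covariance, confidence-interval and variance-inflation-factor (VIF)
  diagnostics, including first-order data-perturbation propagation;
* the CLS reference method (asymmetric-Lorentzian centerlines,
  (bi)exponential decay fit, linear-absorption amplitude step) with the
  **corrected covariance** that propagates Kubo-time uncertainty into the
  absorption step, $V' = V + S V_\tau S^T$;
* a synthetic-data generator with calibrated SNR (noise added to the
  free-induction decay), waiting-time undersampling masks, probe-axis
  relinearization and apodization-window inversion, so that the whole
  pipeline is testable without external data.

## A worked example

Simulate a noisy two-Kubo series in the water-regime fixture and fit all
12 parameters from a random in-bounds start:

```r
library(kubofit)
truth <- params_mescn_h2o()
grid  <- grid_mescn_h2o()      # 16 tau1 x 45 Tw x 64 omega3
ds  <- simulate_dataset(truth, grid, snr = 600, seed = 1)
set.seed(2)
res <- fit_spectrum(ds, p0 = "random", bounds = default_bounds_two_kubo())
print(res)
#> Gauss-Newton fit: converged after 12 iterations, 0 restart(s), cost 0.0895237
#>            estimate      ci95     vif
#> a01          1.0002 5.038e-04   6.158
#> a12          1.1002 5.522e-04   5.865
#> omega01   2162.9988 1.420e-03   2.659
#> d_omega1     0.1513 1.738e-03   2.102
#> anh         25.4966 2.348e-03   1.815
#> tau1         0.3974 1.412e-02 435.268
#> dsq1        12.0269 3.639e-01 784.784
#> tau2         3.5950 3.560e-02  15.448
#> dsq2        10.0179 9.360e-02 230.705
#> beta         1.1004 9.003e-04   3.268
#> inv_t_lt     0.1200 6.588e-05   2.327
#> inv_t_hom    0.4200 2.305e-03 349.904
```

Reading the table: every true value (e.g. $\tau_1 = 0.4$ ps,
$\Delta_1^2 = 12$ cm$^{-2}$, $T_\mathrm{hom}^{-1} = 0.42$ ps$^{-1}$) lies
inside its 95 % confidence half-width; the nondephasing parameters carry
VIFs below 10 (negligible collinearity), while the dephasing block shows
the expected inflation (here up to ~800) that makes *direct* fitting of
these parameters to a linear spectrum — where the same VIFs reach
$10^8$–$10^{12}$ — hopeless.  `cls_pipeline(ds, ...)` runs the CLS
analysis of the same dataset for comparison, and
`vif_scenarios(truth, grid)` reproduces the conditioning hierarchy of the
three strategies.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/kubofit.R simulate --config cfg.yaml --out ds/
Rscript inst/cli/kubofit.R fit      --config cfg.yaml --dataset ds/ --out out/
```

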