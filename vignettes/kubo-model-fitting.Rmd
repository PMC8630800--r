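---
title: "Fitting 2D IR waiting-time series to generalized Kubo line-shape models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting 2D IR waiting-time series to generalized Kubo line-shape models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kubofit)
```

## The problem

Two-dimensional infrared (2D IR) spectroscopy tracks spectral diffusion of a
vibrational probe through the waiting-time evolution of its 2D line shape.
The statistical object of interest is the frequency-fluctuation correlation
function (FFCF).  `kubofit` models it as a generalized Kubo form,

$$\langle\delta\omega_{01}(t)\,\delta\omega_{01}(0)\rangle
  = \frac{\delta(t)}{T_\mathrm{hom}}
  + \sum_i \Delta_i^2\, e^{-t/\tau_i},$$

a motionally narrowed (delta-correlated) homogeneous term plus one or more
exponentially decaying Kubo components with squared amplitudes $\Delta_i^2$
(cm$^{-2}$) and correlation times $\tau_i$ (ps).  The package fits this
model *directly* to the measured waiting-time series in the measurement
domain $(\tau_1, T_w, \omega_3)$, and compares the result against the
popular centerline-slope (CLS) reference method.

## The forward model

The line-shape function is the double time integral of the FFCF,

$$g(t) = t\,T_\mathrm{hom}^{-1}
  + \sum_i \Delta_i^2 (2\pi c)^2 \tau_i^2
    \left[e^{-t/\tau_i} + t/\tau_i - 1\right],$$

with $\Delta_i^2$ converted from cm$^{-2}$ to rad$^2$/ps$^2$ by
$(2\pi c)^2$, $c = 0.0299792458$ cm/ps.  The delta-correlated term is
defined to integrate to exactly $t\,T_\mathrm{hom}^{-1}$, which makes
$T_\mathrm{hom}^{-1}$ the homogeneous Lorentzian half-width rate.

Data are modeled as the isotropic third-order response of a three-level
vibrational system: rephasing and nonrephasing ground-state-bleach and
stimulated-emission pathways with weight $a_{01}$ at $\omega_{01}$, and
excited-state absorption with weight $-a_{12}$ at
$\omega_{01} - \Delta_\mathrm{anh}$.  Within the second-order cumulant
expansion each pathway's dephasing factor is the standard six-term
combination of $g$ evaluated on the three delays.  Because each Kubo term
of $g$ is exponential, the cross-interval memory term factorizes,

$$B(\tau_1, T_w, t_3) = \sum_i \Delta_i^2 (2\pi c)^2 \tau_i^2\,
   e^{-T_w/\tau_i}\!\left(e^{-\tau_1/\tau_i}-1\right)
   \!\left(e^{-t_3/\tau_i}-1\right) \ge 0,$$

and the rephasing/nonrephasing exponents carry $e^{+B}$/$e^{-B}$ — the
photon-echo enhancement.  The compiled core combines $B$ with the diagonal
dephasing exponents *before* exponentiation, so quasi-static components
(large $+B$ against large $-g$) cannot overflow.

Conventions worth stating explicitly:

* **1–2 transition fluctuations.** The 1–2 FFCF is the 0–1 FFCF with its
  Kubo part scaled, $\Delta^2(1\!-\!2) = \beta^2 \Delta^2(0\!-\!1)$, fully
  correlated with the 0–1 fluctuations: cross terms in the cumulant scale
  by $\beta$, pure 1–2 terms by $\beta^2$.  The homogeneous term is shared.
* **1–2 lifetime broadening.** During detection the 1–2 coherence acquires
  the extra dephasing rate
  $\tfrac12\!\left(T_{LT,01}^{-1} + T_{LT,12}^{-1}\right)$ with the
  harmonic default $T_{LT,12} = T_{LT,01}/2$ (exposed as `lt12_ratio`).
* **Population decay** $e^{-T_w\,T_{LT}^{-1}}$ multiplies all pathways,
  including the ground-state bleach.  The exact bleach kinetics are not
  observable separately in this model; treating all pathways alike keeps
  $T_{LT}^{-1}$ a single well-defined decay parameter.
* **Calibration offset.** A pump/probe calibration mismatch is modeled as
  a frequency shift $\delta\omega_1$ during $\tau_1$ *only*; modeling it on
  both axes would be collinear with $\omega_{01}$ and the anharmonicity.
* **Lifetime bound.** $T_\mathrm{hom}^{-1} > \tfrac12 T_{LT}^{-1}$ is
  enforced as a constraint surface, since the homogeneous rate contains
  the lifetime contribution.
* **Probe transform.** The model FID is transformed along $t_3$ only, with
  a unitary DFT whose first time point is half-weighted (trapezoidal/DC
  convention).  Unitarity means white noise has the same standard
  deviation in the time and frequency domains, which makes the SNR
  bookkeeping exact, and the transform exactly invertible.  $t_3$ spacing
  is derived from the probe axis as $1/(N\,\Delta\omega_3\,c)$.

## The fitting engine

The engine minimizes the weighted least-squares cost
$C(\mathbf p) = \mathbf r^T \mathbf V_D^{-1} \mathbf r$,
$\mathbf r = \mathbf D - \mathbf M(\mathbf p)$, with diagonal
inverse-variance weights.  Each iteration computes a central-difference
Jacobian (exactly $2N_p$ model evaluations; step
$10^{-4}\max(|p_k|, 0.01\,\mathrm{width}_k)$), the Gauss–Newton system
$\nabla\nabla C = 2 J^T V_D^{-1} J$,
$\nabla C = -2\mathbf r^T V_D^{-1} J$, solves for the step, corrects it by
the parameter box and the lifetime constraint, and line-searches along the
corrected direction under the Armijo condition ($c_1 = 10^{-4}$, halving,
25 backtracks).

Two numerical choices matter here and were made deliberately:

* **Jacobi preconditioning.**  The normal equations are scaled to unit
  diagonal before solving and before the reciprocal-condition test
  (threshold $10^{-12}$).  Parameters span five orders of magnitude in
  natural units (2163 cm$^{-1}$ vs 0.01 ps$^{-1}$); without the scaling
  the condition estimate measures units, not collinearity, and healthy
  steps get rejected as singular.
* **Boundary correction before the line search.**  The step is projected
  onto the feasible box first and the Armijo search runs along the
  corrected direction (the feasible set is convex, so backtracked points
  stay feasible).  This preserves the descent property exactly — accepted
  iterations never increase $C$ — and makes boundary stalling
  well-defined: if even the corrected direction cannot decrease the cost,
  the iteration is stalled at a boundary.

**Stopping** uses the scale-invariant gradient norm,

$$\mathrm{SIGN}_i = \frac{\lVert \nabla C(\mathbf p_i) \odot
  \boldsymbol\sigma_p(\mathbf p_i)\rVert}{C(\mathbf p_{i-1})},$$

the elementwise product of the gradient with the per-parameter standard
errors, normalized by the previous iteration's cost (better behaved across
restarts).  SIGN is invariant to rescaling data and model by a common
factor, to rescaling the weights, and to the number of data points, so the
default threshold transfers across problems.  The fit stops when the last
three iterations have SIGN $< 10^{-9}$ and costs within 10 % of the best
cost seen.  An elementwise-product norm is used rather than the scalar
product $|\nabla C \cdot \boldsymbol\sigma_p|$, which can cancel between
parameters of opposite gradient sign; the scalar reading is exposed via
`fit_options(sign_variant = "scalar")` for comparison.  A perfect-fit
short-circuit (cost below $10^{-24}$ of the data scale) handles noiseless
round trips, whose cost collapses to the arithmetic floor where a relative
window is meaningless.

**Stalling** — step collapse with a nonzero gradient, from boundaries or
ill-conditioning — is declared when SIGN and cost both vary by less than
1 % over three iterations, or immediately on a (nearly) singular system or
a failed line search.  Stalls are resolved by a uniform random restart
within the user bounds (budget 20), and the best-ever parameters are
retained.  Degenerate Kubo pairs ($\tau_1 \approx \tau_2$) are the classic
stall driver: the amplitudes become linearly dependent, the VIFs blow up,
and the program restarts rather than grinding.

## Uncertainty and multicollinearity

The parameter covariance is
$V_p = \frac{C(\hat{\mathbf p})}{N_D - N_p}\,(J^T V_D^{-1} J)^{-1}$;
the reduced-$\chi^2$ prefactor absorbs the unknown proportionality constant
of the weights, so only weight *ratios* matter.  Confidence intervals use
normal quantiles ($N_D \gg N_p$ throughout).

Variance inflation factors are computed from the column-normalized
Jacobian: with $\hat J$ scaled so $\mathrm{diag}(\hat J^T V_D^{-1}\hat J)
= 1$, the VIF of parameter $i$ is the $i$-th diagonal of the *true* inverse
of that Gram matrix (a pseudo-inverse would mask the collinearity blow-up;
values above $10^{12}$ raise a condition flag).  First-order propagation of
a data perturbation is $d\mathbf p = (J^T W J)^{-1} J^T W\, d\mathbf D$.

## The CLS reference pipeline

For each waiting time, the absorptive spectrum on a pump-frequency axis is
obtained by an explicit discrete Fourier evaluation over $\tau_1$
(half-weighted first point); probe-axis slices whose maximum reaches 50 %
of the global maximum are fitted with an asymmetric Lorentzian
(Lorentzian + linear + offset) within $\pm 1.5$ apparent FWHM of the 0–1
band (floored above the midpoint to the 1–2 band), and the extremum of the
fitted function — not the maximum bin — gives the centerline point.  The
CLS is the unweighted regression slope of those points against pump
frequency.  A (bi)exponential fit to CLS($T_w$), including $T_w = 0$,
yields the Kubo time constants; absolute amplitudes and the homogeneous
rate come from a second fit to the upper 80 % of the linear absorption
spectrum with the times held fixed and, for multi-component models, the
relative $\Delta_i^2$ fractions fixed at the CLS amplitude fractions
(standard CLS practice; the slice-fit windows and thresholds are exposed
in the function arguments).

The standard covariance of that absorption step pretends the fixed times
are exact.  The corrected (modified) covariance adds the propagated
time-constant uncertainty,
$V' = V + S\,V_\tau\,S^T$, where $S = \partial\hat{\mathbf p}/
\partial\boldsymbol\tau$ is measured by refitting with each $\tau$
perturbed $\pm 1\%$.  On realistic inputs the inflation spans orders of
magnitude, which is the quantitative statement of why CLS error bars on
Kubo amplitudes and homogeneous dephasing are underestimated.

## The synthetic-data generator

`simulate_dataset()` defines the study conditions.  Gaussian noise is
added to both quadratures of the free-induction decay *before* the probe
transform, with
$\sigma = \mathrm{peak}\,|\mathrm{TA}(T_w = 0)|/\mathrm{SNR}$ — signal
defined as the 0–1 peak magnitude of the zero-waiting-time transient
absorption.  Since the transform is unitary, the realized peak-to-noise
ratio of the dataset equals the requested SNR.  Real-valued detection
keeps the real quadrature; complex detection keeps both (fitted as stacked
quadratures).  Waiting-time undersampling masks keep every $k$-th point
outward from a 1 ps pivot, always retain the pivot-nearest and final
points, and exclude the pulse-overlap window ($T_w < 0.3$ ps); on the
47-point experiment-like axis the stride-1 and stride-3 masks keep 45 and
15 points.  Preprocessing helpers cover cubic-spline relinearization of a
spectrograph probe axis (FMM end conditions, exact on cubics) and
inversion of apodization windows with a relative floor (5 % of the window
maximum; sub-floor points are zeroed and flagged so their weights can be
zeroed) and an optional half-scaled-DC restoration.

What the generator does *not* emulate: correlated (local-oscillator)
noise, scatter and phase-cycling artifacts, structured solvent responses,
baseline distortions of measured absorption spectra, or orientational
dynamics.  Passing tests therefore demonstrate correctness of the
estimator under uncorrelated Gaussian noise and a correctly specified
line-shape model — not robustness to the structured residuals real
measurements contain.

## Study conditions and fixture

The benchmark regime is a small thiocyanate probe in water.
No parameter table for that simulation is available to this package, so
the fixture was chosen once from the regime's literature description and
is frozen as `params_mescn_h2o()`:
$\omega_{01} = 2163$ cm$^{-1}$, $\Delta_\mathrm{anh} = 25.5$ cm$^{-1}$,
$a_{01} = 1$, $a_{12} = 1.1$, $\delta\omega_1 = 0.15$ cm$^{-1}$,
$\beta = 1.1$, $T_{LT}^{-1} = 0.12$ ps$^{-1}$,
$T_\mathrm{hom}^{-1} = 0.42$ ps$^{-1}$, and two Kubo components
$(\Delta^2, \tau) = (12\ \mathrm{cm}^{-2}, 0.4\ \mathrm{ps})$ and
$(10\ \mathrm{cm}^{-2}, 3.6\ \mathrm{ps})$: a fast, partially motionally
narrowed hydrogen-bond component and a slower structural component.  The
companion grid (`grid_mescn_h2o()`) is 16 pump delays at 250 fs, 45
waiting times from 0 to 12 ps (dense early), and 64 probe points at
1.5 cm$^{-1}$ — about $4.6\times10^4$ data points, sized so that a
100-trial ensemble runs on a desk machine in minutes.  A slow-modulation
one-Kubo example from a published DMSO fit is frozen as
`params_mescn_dmso()`.

The simulation study (`simulation_study()`, summarized by
`study_metrics()`) fits every noise realization from a *random* in-bounds
start and analyzes the same realizations with the CLS pipeline against the
noiseless simulated absorption spectrum (the CLS best case).  The fitting
bounds follow the recommended practice of splitting the two Kubo times
onto different time scales (0.05–2 ps and 1–20 ps) with overlap, so that
degenerate pairs are rare but reachable.

Under these committed conditions, model fitting is dramatically more
precise than CLS for the *amplitude* and *homogeneous* parameters, and the
CLS estimates of the fast component are strongly biased (its
motional-narrowing suppression of the early CLS amplitude is the textbook
failure of the short-time approximation).  For the *slow* Kubo time
constant the CLS decay fit is comparatively well conditioned on this
grid, and the measured CLS/model precision ratio for that parameter can
sit below the 8-fold figure quoted for the reference regime; the ratio is
reported as computed, not tuned.

## Numerical choices and limitations

* Linear absorption uses direct quadrature of the dipole correlation
  function on a time grid with phase steps $\le 0.1$ rad and an envelope
  cutoff at $e^{-32}$, capped at 2 ns (residual linewidth below
  $3\times10^{-3}$ cm$^{-1}$, far under any realistic resolution), in
  frequency chunks to bound memory.
* The engine's near-singularity threshold ($10^{-12}$ reciprocal
  condition) and the huge-VIF threshold ($10^{12}$) are floating-point
  pragmatics: exact infinities are unreachable.
* `fit_cls_decay` multi-starts over a logarithmic grid of time-constant
  pairs; a flat decay returns the static-offset branch with the times
  flagged non-identifiable.
* Degenerate inputs (monotonic slices, all-zero spectra, empty fit
  windows, zero apodization windows, masks with fewer than two points)
  are rejected with explicit errors rather than propagated.
* The model is an isotropic three-level response: no coupled oscillators,
  overlapping ensembles, oscillatory FFCFs, or polarization-resolved
  observables.  Correlated noise is not representable in the diagonal
  weight model (the full data covariance would be prohibitively large);
  weights cover nonuniform averaging only.

## A minimal session

```{r example, eval = FALSE}
truth <- params_mescn_h2o()
grid <- grid_mescn_h2o()
ds <- simulate_dataset(truth, grid, snr = 600, seed = 1)
res <- fit_spectrum(ds, p0 = "random", bounds = default_bounds_two_kubo())
print(res)

cls <- cls_pipeline(ds, n_exp = 2,
                    absorption = list(omega = seq(2123, 2203, 1),
                                      absorbance = linear_absorption(
                                        truth, seq(2123, 2203, 1))),
                    inv_t_lt = truth$inv_t_lt, modified = TRUE)
print(cls)
```
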