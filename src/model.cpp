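#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double C_CM_PS  = 0.0299792458;        // speed of light, cm/ps
static const double TWO_PI_C = 2.0 * M_PI * C_CM_PS; // cm^-1 -> rad/ps

// Kubo part of the line-shape function on a vector of times.
// kubo: k x 2 matrix, columns (delta_sq [cm^-2], tau [ps]).
static vec g_kubo_vec(const vec& t, const mat& kubo) {
  vec g(t.n_elem, fill::zeros);
  for (uword i = 0; i < kubo.n_rows; ++i) {
    const double dsq = kubo(i, 0) * TWO_PI_C * TWO_PI_C; // rad^2/ps^2
    const double tau = kubo(i, 1);
    g += dsq * tau * tau * (exp(-t / tau) + t / tau - 1.0);
  }
  return g;
}

// Complex third-order free-induction decay of a three-level system over
// (tau1, tw, t3).  Sum of rephasing and nonrephasing ground-state-bleach /
// stimulated-emission pathways (weight a01, at omega01) and excited-state
// absorption (weight -a12, at omega01 - anh).  The cross-interval memory
// term B factorizes over the Kubo components:
//   B(tau1, Tw, t3) = sum_i Dsq_i tau_i^2 e^{-Tw/tau_i}
//                       (e^{-tau1/tau_i} - 1)(e^{-t3/tau_i} - 1)  >= 0,
// and the rephasing/nonrephasing exponents carry exp(+B)/exp(-B); the ESA
// pathways scale the t3-interval fluctuations by beta (cross terms by beta,
// pure 1-2 terms by beta^2).
// [[Rcpp::export]]
arma::cx_cube fid_cube_cpp(const arma::vec& tau1, const arma::vec& tw,
                           const arma::vec& t3,
                           double a01, double a12, double omega01,
                           double d_omega1, double anh, double beta,
                           double inv_t_lt, double inv_t_hom, double phi0,
                           double esa_rate_add, const arma::mat& kubo,
                           double omega_rf) {
  const uword n1 = tau1.n_elem, n2 = tw.n_elem, n3 = t3.n_elem;
  const std::complex<double> I(0.0, 1.0);

  const double om1p = (omega01 + d_omega1 - omega_rf) * TWO_PI_C; // pump, rad/ps
  const double om01 = (omega01 - omega_rf) * TWO_PI_C;            // 0-1 probe
  const double om12 = (omega01 - anh - omega_rf) * TWO_PI_C;      // 1-2 probe

  const vec gk1 = g_kubo_vec(tau1, kubo);
  const vec gk3 = g_kubo_vec(t3, kubo);

  // real dephasing exponents and unit phase factors kept separate; the
  // cross-interval term B is combined with them inside the loop BEFORE
  // exponentiation so quasi-static components (large +B against large -g)
  // cannot overflow
  vec g1(n1);
  cx_vec U1(n1);
  for (uword a = 0; a < n1; ++a) {
    g1(a) = inv_t_hom * tau1(a) + gk1(a);
    U1(a) = std::exp(I * om1p * tau1(a));
  }
  vec g301(n3), g312(n3);
  cx_vec U01(n3), U12(n3);
  for (uword c = 0; c < n3; ++c) {
    g301(c) = inv_t_hom * t3(c) + gk3(c);
    g312(c) = (inv_t_hom + esa_rate_add) * t3(c) + beta * beta * gk3(c);
    U01(c) = std::exp(-I * om01 * t3(c));
    U12(c) = std::exp(-I * om12 * t3(c));
  }

  const vec pop = exp(-inv_t_lt * tw); // population decay, all pathways
  const std::complex<double> ph0 = std::exp(I * phi0);

  // per-component separable factors of B
  const uword nk = kubo.n_rows;
  mat ea1(n1, nk), eT(n2, nk), ec3(n3, nk);
  vec coef(nk);
  for (uword i = 0; i < nk; ++i) {
    const double tau = kubo(i, 1);
    coef(i) = kubo(i, 0) * TWO_PI_C * TWO_PI_C * tau * tau;
    ea1.col(i) = exp(-tau1 / tau) - 1.0;
    eT.col(i)  = exp(-tw / tau);
    ec3.col(i) = exp(-t3 / tau) - 1.0;
  }

  cx_cube out(n1, n2, n3);
  for (uword c = 0; c < n3; ++c) {
    for (uword b = 0; b < n2; ++b) {
      for (uword a = 0; a < n1; ++a) {
        double B = 0.0;
        for (uword i = 0; i < nk; ++i)
          B += coef(i) * eT(b, i) * ea1(a, i) * ec3(c, i);
        const std::complex<double> U = U1(a), Uc = std::conj(U);
        const double e01 = g1(a) + g301(c);
        const double e12 = g1(a) + g312(c);
        const std::complex<double> s01 =
          U * std::exp(B - e01) + Uc * std::exp(-B - e01);
        const std::complex<double> s12 =
          U * std::exp(beta * B - e12) + Uc * std::exp(-beta * B - e12);
        out(a, b, c) = pop(b) * ph0 *
          (a01 * U01(c) * s01 - a12 * U12(c) * s12);
      }
    }
  }
  return out;
}

// Unitary discrete Fourier transform along t3 mapping the free-induction
// decay onto the probe-frequency axis.  The first time point carries weight
// 1/2 (trapezoidal/DC convention) and the overall 1/sqrt(N) scaling keeps
// white noise variance identical in both domains.
// [[Rcpp::export]]
arma::cx_mat probe_dft_matrix_cpp(const arma::vec& t3, const arma::vec& omega3,
                                  double omega_rf) {
  const uword n3 = t3.n_elem, nk = omega3.n_elem;
  const std::complex<double> I(0.0, 1.0);
  cx_mat W(n3, nk);
  const double s = 1.0 / std::sqrt(static_cast<double>(n3));
  for (uword k = 0; k < nk; ++k) {
    const double om = (omega3(k) - omega_rf) * TWO_PI_C;
    for (uword c = 0; c < n3; ++c) {
      const double w = (c == 0) ? 0.5 : 1.0;
      W(c, k) = w * s * std::exp(I * om * t3(c));
    }
  }
  return W;
}

// Fused real-mode forward model: FID assembly and probe-axis DFT in one
// pass, returning only the real (absorptive-detection) part as a
// (n1*n2) x n_omega3 matrix.  Re(F W) = [Re F, Im F] [Re W; -Im W] costs a
// single real GEMM.
// [[Rcpp::export]]
arma::mat spectrum_real_cpp(const arma::vec& tau1, const arma::vec& tw,
                            const arma::vec& t3,
                            double a01, double a12, double omega01,
                            double d_omega1, double anh, double beta,
                            double inv_t_lt, double inv_t_hom, double phi0,
                            double esa_rate_add, const arma::mat& kubo,
                            const arma::vec& omega3, double omega_rf) {
  const uword n1 = tau1.n_elem, n2 = tw.n_elem, n3 = t3.n_elem;
  const std::complex<double> I(0.0, 1.0);
  const double om1p = (omega01 + d_omega1 - omega_rf) * TWO_PI_C;
  const double om01 = (omega01 - omega_rf) * TWO_PI_C;
  const double om12 = (omega01 - anh - omega_rf) * TWO_PI_C;

  const vec gk1 = g_kubo_vec(tau1, kubo);
  const vec gk3 = g_kubo_vec(t3, kubo);
  vec g1(n1);
  cx_vec U1(n1);
  for (uword a = 0; a < n1; ++a) {
    g1(a) = inv_t_hom * tau1(a) + gk1(a);
    U1(a) = std::exp(I * om1p * tau1(a));
  }
  vec g301(n3), g312(n3);
  cx_vec U01(n3), U12(n3);
  for (uword c = 0; c < n3; ++c) {
    g301(c) = inv_t_hom * t3(c) + gk3(c);
    g312(c) = (inv_t_hom + esa_rate_add) * t3(c) + beta * beta * gk3(c);
    U01(c) = std::exp(-I * om01 * t3(c));
    U12(c) = std::exp(-I * om12 * t3(c));
  }
  const vec pop = exp(-inv_t_lt * tw);
  const std::complex<double> ph0 = std::exp(I * phi0);

  const uword nk = kubo.n_rows;
  mat ea1(n1, nk), eT(n2, nk), ec3(n3, nk);
  vec coef(nk);
  for (uword i = 0; i < nk; ++i) {
    const double tau = kubo(i, 1);
    coef(i) = kubo(i, 0) * TWO_PI_C * TWO_PI_C * tau * tau;
    ea1.col(i) = exp(-tau1 / tau) - 1.0;
    eT.col(i)  = exp(-tw / tau);
    ec3.col(i) = exp(-t3 / tau) - 1.0;
  }

  mat FR(n1 * n2, 2 * n3);
  for (uword c = 0; c < n3; ++c) {
    for (uword b = 0; b < n2; ++b) {
      const std::complex<double> f01 = ph0 * a01 * U01(c) * pop(b);
      const std::complex<double> f12 = ph0 * a12 * U12(c) * pop(b);
      for (uword a = 0; a < n1; ++a) {
        double B = 0.0;
        for (uword i = 0; i < nk; ++i)
          B += coef(i) * eT(b, i) * ea1(a, i) * ec3(c, i);
        const std::complex<double> U = U1(a), Uc = std::conj(U);
        const double e01 = g1(a) + g301(c);
        const double e12 = g1(a) + g312(c);
        const std::complex<double> val =
          f01 * (U * std::exp(B - e01) + Uc * std::exp(-B - e01)) -
          f12 * (U * std::exp(beta * B - e12) + Uc * std::exp(-beta * B - e12));
        FR(a + n1 * b, c) = val.real();
        FR(a + n1 * b, n3 + c) = val.imag();
      }
    }
  }
  const cx_mat W = probe_dft_matrix_cpp(t3, omega3, omega_rf);
  mat WR(2 * n3, omega3.n_elem);
  WR.rows(0, n3 - 1) = real(W);
  WR.rows(n3, 2 * n3 - 1) = -imag(W);
  return FR * WR;
}

// FID cube -> spectrum cube (tau1, tw, omega3): DFT along the third axis.
// [[Rcpp::export]]
arma::cx_cube spectrum_from_fid_cpp(const arma::cx_cube& fid,
                                    const arma::vec& t3,
                                    const arma::vec& omega3,
                                    double omega_rf) {
  const uword n1 = fid.n_rows, n2 = fid.n_cols, n3 = fid.n_slices;
  const cx_mat W = probe_dft_matrix_cpp(t3, omega3, omega_rf);
  cx_mat flat(n1 * n2, n3);
  for (uword c = 0; c < n3; ++c)
    flat.col(c) = vectorise(fid.slice(c));
  cx_mat res = flat * W; // (n1*n2) x nk
  cx_cube out(n1, n2, omega3.n_elem);
  for (uword k = 0; k < omega3.n_elem; ++k)
    out.slice(k) = reshape(res.col(k), n1, n2);
  return out;
}
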