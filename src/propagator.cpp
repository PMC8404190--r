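// Split-operator kernels for coupled-surface wave-packet propagation and
// the first-order photoelectron signal.
//
// Conventions: grids are n1 x n2 arma::cx_mat (column-major, R1 fastest),
// flattened column-major where vectors are needed.  All quantities in
// Hartree atomic units.  The kinetic operator is spectral:
// T = k1^2/(2 m1) + k2^2/(2 m2) on the FFT frequency grid.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat kinetic_grid(const vec& k1, const vec& k2, double m1, double m2) {
  mat kin(k1.n_elem, k2.n_elem);
  for (uword j = 0; j < k2.n_elem; ++j)
    for (uword i = 0; i < k1.n_elem; ++i)
      kin(i, j) = 0.5 * k1(i) * k1(i) / m1 + 0.5 * k2(j) * k2(j) / m2;
  return kin;
}

static cx_mat phase_of(const mat& x, double factor) {
  // exp(i * factor * x)
  return cx_mat(cos(factor * x), sin(factor * x));
}

// exp(-i dt [[V0, W], [W, V1]]) in closed form (Pauli decomposition):
// M = mbar I - delta sigma_z + W sigma_x, r = sqrt(delta^2 + W^2),
// exp(-i dt M) = e^{-i dt mbar} [cos(dt r) I - i sin(dt r)/r (W sx - delta sz)]
struct PotProp {
  cx_mat U00, U11, U01;
  void build(const mat& V0, const mat& V1, const mat& W, double dt) {
    mat mbar = 0.5 * (V0 + V1);
    mat delta = 0.5 * (V1 - V0);
    mat r = sqrt(square(delta) + square(W));
    cx_mat ph = phase_of(mbar, -dt);
    mat c = cos(dt * r);
    mat sinc(r.n_rows, r.n_cols);
    for (uword i = 0; i < r.n_elem; ++i)
      sinc(i) = (r(i) > 1e-300) ? std::sin(dt * r(i)) / r(i) : dt;
    cx_mat zero(size(c), fill::zeros);
    cx_mat cc = cx_mat(c, mat(size(c), fill::zeros));
    cx_mat is = cx_mat(mat(size(c), fill::zeros), -sinc);
    cx_mat dd = cx_mat(delta, mat(size(c), fill::zeros));
    cx_mat ww = cx_mat(W, mat(size(c), fill::zeros));
    // exp(-i dt (n.sigma)) = cos I - i sin (W sx - delta sz)/r;
    // (sz)_00 = +1, so the 00 entry gets + i sin delta / r.
    U00 = ph % (cc - is % dd);
    U11 = ph % (cc + is % dd);
    U01 = ph % (is % ww);
  }
  void apply(cx_mat& a, cx_mat& b) const {
    cx_mat na = U00 % a + U01 % b;
    b = U01 % a + U11 % b;
    a = std::move(na);
  }
};

static inline void kin_apply(cx_mat& psi, const cx_mat& phase) {
  psi = ifft2(fft2(psi) % phase);
}

// ---------------------------------------------------------------------------
// Imaginary-time relaxation on a single surface.
// [[Rcpp::export]]
Rcpp::List cpp_relax(const arma::mat& V0, double m1, double m2,
                     double d1, double d2,
                     const arma::vec& k1, const arma::vec& k2,
                     double dt, double tol, int max_steps) {
  const uword n1 = V0.n_rows, n2 = V0.n_cols;
  const double dVol = d1 * d2;
  const double N = double(n1) * double(n2);
  mat kin = kinetic_grid(k1, k2, m1, m2);
  cx_mat half = cx_mat(exp(-0.5 * dt * kin), mat(size(kin), fill::zeros));
  cx_mat potf = cx_mat(exp(-dt * V0), mat(size(V0), fill::zeros));

  // Gaussian seed centred at the potential minimum
  uword imin = V0.index_min();
  uword i0 = imin % n1, j0 = imin / n1;
  double s1 = n1 * d1 / 12.0, s2 = n2 * d2 / 12.0;
  cx_mat psi(n1, n2);
  for (uword j = 0; j < n2; ++j)
    for (uword i = 0; i < n1; ++i) {
      double x = (double(i) - double(i0)) * d1, y = (double(j) - double(j0)) * d2;
      psi(i, j) = std::exp(-x * x / (2 * s1 * s1) - y * y / (2 * s2 * s2));
    }
  psi /= std::sqrt(accu(square(abs(psi))) * dVol);

  double e_prev = datum::inf, energy = 0, dE = datum::inf;
  int it = 0;
  for (it = 0; it < max_steps; ++it) {
    kin_apply(psi, half);
    psi %= potf;
    kin_apply(psi, half);
    psi /= std::sqrt(accu(square(abs(psi))) * dVol);
    cx_mat ph = fft2(psi);
    double Tq = accu(kin % square(abs(ph))) * dVol / N;
    double Vq = accu(V0 % square(abs(psi))) * dVol;
    energy = Tq + Vq;
    dE = std::abs(energy - e_prev);
    e_prev = energy;
    if (dE < tol && it > 2) break;
  }

  return Rcpp::List::create(
    Rcpp::Named("psi") = psi,
    Rcpp::Named("energy") = energy,
    Rcpp::Named("iterations") = it + 1,
    Rcpp::Named("converged") = dE < tol,
    Rcpp::Named("dE") = dE);
}

// ---------------------------------------------------------------------------
// Real-time propagation of the two-component packet (Strang splitting:
// half kinetic, full coupled potential, half kinetic, then the absorbing
// mask).  Records per-step populations, snapshots at snap_stride and the
// ionization source mu * (psi0 + psi1) at src_stride.
// [[Rcpp::export]]
Rcpp::List cpp_propagate(const arma::mat& V0, const arma::mat& V1,
                         const arma::mat& W, const arma::mat& cap,
                         arma::cx_mat psi0, arma::cx_mat psi1,
                         double m1, double m2, double d1, double d2,
                         const arma::vec& k1, const arma::vec& k2,
                         double dt, int n_steps,
                         int snap_stride, int src_stride,
                         double mu, bool collect_source) {
  const uword n1 = V0.n_rows, n2 = V0.n_cols;
  const double dVol = d1 * d2;
  mat kin = kinetic_grid(k1, k2, m1, m2);
  cx_mat half = phase_of(kin, -0.5 * dt);
  PotProp pot;
  pot.build(V0, V1, W, dt);
  const bool has_cap = any(vectorise(cap) != 0);
  mat mask = exp(-dt * cap);

  const int n_snap = n_steps / snap_stride + 1;
  const int n_src = collect_source ? (n_steps / src_stride + 1) : 1;
  cx_cube snap0(n1, n2, n_snap), snap1(n1, n2, n_snap);
  cx_mat src(collect_source ? n1 * n2 : 1, n_src);
  vec pop0(n_steps + 1), pop1(n_steps + 1), absorbed(n_steps + 1);

  double lost = 0;
  auto record_pop = [&](int s) {
    pop0(s) = accu(square(abs(psi0))) * dVol;
    pop1(s) = accu(square(abs(psi1))) * dVol;
    absorbed(s) = lost;
  };
  record_pop(0);
  snap0.slice(0) = psi0; snap1.slice(0) = psi1;
  if (collect_source) src.col(0) = mu * vectorise(psi0 + psi1);

  int isnap = 1, isrc = 1;
  for (int s = 1; s <= n_steps; ++s) {
    kin_apply(psi0, half);
    kin_apply(psi1, half);
    pot.apply(psi0, psi1);
    kin_apply(psi0, half);
    kin_apply(psi1, half);
    if (has_cap) {
      double before = (accu(square(abs(psi0))) + accu(square(abs(psi1)))) * dVol;
      psi0 %= conv_to<cx_mat>::from(mask);
      psi1 %= conv_to<cx_mat>::from(mask);
      double after = (accu(square(abs(psi0))) + accu(square(abs(psi1)))) * dVol;
      lost += before - after;
    }
    record_pop(s);
    if (s % snap_stride == 0 && isnap < n_snap) {
      snap0.slice(isnap) = psi0; snap1.slice(isnap) = psi1; ++isnap;
    }
    if (collect_source && s % src_stride == 0 && isrc < n_src) {
      src.col(isrc) = mu * vectorise(psi0 + psi1); ++isrc;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("psi0") = psi0, Rcpp::Named("psi1") = psi1,
    Rcpp::Named("snap0") = snap0, Rcpp::Named("snap1") = snap1,
    Rcpp::Named("source") = src,
    Rcpp::Named("pop0") = pop0, Rcpp::Named("pop1") = pop1,
    Rcpp::Named("absorbed") = absorbed);
}

// ---------------------------------------------------------------------------
// Single Strang step of the coupled system (exposed for unit tests and
// for step-wise driving from R).
// [[Rcpp::export]]
Rcpp::List cpp_step(const arma::mat& V0, const arma::mat& V1,
                    const arma::mat& W, const arma::mat& cap,
                    const arma::cx_mat& psi0_in, const arma::cx_mat& psi1_in,
                    double m1, double m2,
                    const arma::vec& k1, const arma::vec& k2, double dt) {
  cx_mat psi0 = psi0_in, psi1 = psi1_in;
  if (dt != 0) {
    mat kin = kinetic_grid(k1, k2, m1, m2);
    cx_mat half = phase_of(kin, -0.5 * dt);
    PotProp pot;
    pot.build(V0, V1, W, dt);
    kin_apply(psi0, half);
    kin_apply(psi1, half);
    pot.apply(psi0, psi1);
    kin_apply(psi0, half);
    kin_apply(psi1, half);
    if (any(vectorise(cap) != 0)) {
      mat mask = exp(-dt * cap);
      psi0 %= conv_to<cx_mat>::from(mask);
      psi1 %= conv_to<cx_mat>::from(mask);
    }
  }
  return Rcpp::List::create(Rcpp::Named("psi0") = psi0,
                            Rcpp::Named("psi1") = psi1);
}

// ---------------------------------------------------------------------------
// Banded Gram matrix of ion-surface-propagated ionization sources.
//
// G(tau, j) = <U^tau g_j, g_{j+tau}> * dVol for tau = 0..max_lag, where
// U = exp(-i dt (T + Veff)) is one Strang step on the ionized surface and
// g_j are the source snapshots (columns of `src`).  The photoelectron
// signal for ANY probe envelope and any delay/energy grid is a quadratic
// form in this band, so the expensive propagation is done exactly once
// per trajectory.
//
// The Strang step factorizes as U = A B A (A = half kinetic, B =
// potential).  Using unitarity, <A X g_i, g_j> = <X g_i, A^{-1} g_j>, so
// active columns are kept in the mid-representation u_i = (B A^2)^k B A g_i
// (one FFT pair per column per step) and each incoming snapshot is paired
// as a_j = A^{-1} g_j.
// [[Rcpp::export]]
arma::cx_mat cpp_band_gram(const arma::cx_mat& src, const arma::mat& Veff,
                           double m1, double m2, double d1, double d2,
                           const arma::vec& k1, const arma::vec& k2,
                           double dt, int max_lag) {
  const uword n1 = Veff.n_rows, n2 = Veff.n_cols;
  const uword ng = n1 * n2;
  const uword ns = src.n_cols;
  if (src.n_rows != ng) Rcpp::stop("cpp_band_gram: source/grid size mismatch");
  const int L = std::min<int>(max_lag, int(ns) - 1);
  const double dVol = d1 * d2;

  mat kin = kinetic_grid(k1, k2, m1, m2);
  cx_mat half = phase_of(kin, -0.5 * dt);   // A
  cx_mat ihalf = phase_of(kin, 0.5 * dt);   // A^{-1}
  cx_mat full = phase_of(kin, -dt);         // A^2
  cx_mat potf = phase_of(Veff, -dt);        // B

  cx_mat G(L + 1, ns, fill::zeros);
  cx_mat U(ng, L, fill::zeros);   // ring buffer of active columns
  std::vector<int> owner(L, -1);  // source index held in each slot

  cx_mat work(n1, n2);
  for (uword j = 0; j < ns; ++j) {
    // bra partner a_j = A^{-1} g_j
    work = reshape(src.col(j), n1, n2);
    kin_apply(work, ihalf);
    cx_vec a = vectorise(work);

    G(0, j) = cdot(src.col(j), src.col(j)) * dVol;
    for (int s = 0; s < L; ++s) {
      if (owner[s] < 0) continue;
      int tau = int(j) - owner[s];
      if (tau >= 1 && tau <= L)
        G(tau, owner[s]) = cdot(U.col(s), a) * dVol;
    }

    if (L == 0) continue;
    // advance active columns by one full step (B A^2)
    for (int s = 0; s < L; ++s) {
      if (owner[s] < 0) continue;
      if (int(j) - owner[s] >= L) { owner[s] = -1; continue; }
      work = reshape(U.col(s), n1, n2);
      kin_apply(work, full);
      work %= potf;
      U.col(s) = vectorise(work);
    }
    // insert the new column as B A g_j
    int slot = int(j) % L;
    work = reshape(src.col(j), n1, n2);
    kin_apply(work, half);
    work %= potf;
    U.col(slot) = vectorise(work);
    owner[slot] = int(j);
  }
  return G;
}

// ---------------------------------------------------------------------------
// Direct source-term propagation on the ionized surface for one
// (delay, photoelectron-energy) pair: i d/dt psi = (T + Veff) psi + w(t) g(t),
// discretized as psi_k = U psi_{k-1} - i dt w_k g_k.  Returns the final
// norm^2 (the integrated photoelectron current into that energy bin).
// Serves as the independent slow route checking the Gram-based spectrogram.
// [[Rcpp::export]]
double cpp_source_signal(const arma::cx_mat& src, const arma::cx_vec& weights,
                         const arma::mat& Veff,
                         double m1, double m2, double d1, double d2,
                         const arma::vec& k1, const arma::vec& k2, double dt) {
  const uword n1 = Veff.n_rows, n2 = Veff.n_cols;
  if (src.n_rows != n1 * n2) Rcpp::stop("cpp_source_signal: size mismatch");
  if (src.n_cols != weights.n_elem) Rcpp::stop("cpp_source_signal: weight length mismatch");
  mat kin = kinetic_grid(k1, k2, m1, m2);
  cx_mat half = phase_of(kin, -0.5 * dt);
  cx_mat potf = phase_of(Veff, -dt);

  cx_mat psi(n1, n2, fill::zeros);
  for (uword j = 0; j < src.n_cols; ++j) {
    kin_apply(psi, half);
    psi %= potf;
    kin_apply(psi, half);
    psi += cx_double(0, -dt) * weights(j) * reshape(src.col(j), n1, n2);
  }
  return accu(square(abs(psi))) * d1 * d2;
}
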