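// Numerical core for the canonical-microcircuit (CMC) neural mass model:
//  - frequency-domain transfer functions and cross-spectral densities of the
//    linearized delay system (delays enter as exact phase factors), and
//  - a fixed-step delay-aware RK4 integrator of the nonlinear equations of
//    motion used for simulation and as an oracle for the spectral code.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Resolvent-based transfer functions of the linearized delay system.
// A0 holds instantaneous terms, Ai / Ae the couplings conducted with the
// intrinsic / extrinsic delay (seconds).  T(f) = L (i w I - A(w))^-1 B with
// A(w) = A0 + Ai exp(-i w tau_i) + Ae exp(-i w tau_e), w = 2 pi f.
// [[Rcpp::export]]
arma::cx_cube cmc_transfer_cpp(const arma::mat& A0, const arma::mat& Ai,
                               const arma::mat& Ae, const arma::mat& B,
                               const arma::mat& L, double tau_i, double tau_e,
                               const arma::vec& freq) {
  const uword n = A0.n_rows, nu = B.n_cols, nc = L.n_rows, nf = freq.n_elem;
  cx_cube out(nc, nu, nf);
  cx_mat A0c = conv_to<cx_mat>::from(A0), Aic = conv_to<cx_mat>::from(Ai),
         Aec = conv_to<cx_mat>::from(Ae), Bc = conv_to<cx_mat>::from(B),
         Lc = conv_to<cx_mat>::from(L);
  cx_mat M(n, n);
  for (uword k = 0; k < nf; ++k) {
    double w = 2.0 * datum::pi * freq(k);
    std::complex<double> ei = std::exp(std::complex<double>(0.0, -w * tau_i));
    std::complex<double> ee = std::exp(std::complex<double>(0.0, -w * tau_e));
    M = -A0c - ei * Aic - ee * Aec;
    M.diag() += std::complex<double>(0.0, w);
    cx_mat K;
    bool ok = solve(K, M, Bc, solve_opts::no_approx);
    if (!ok) Rcpp::stop("singular resolvent at frequency %f Hz", freq(k));
    out.slice(k) = Lc * K;
  }
  return out;
}

// Predicted cross-spectral density over channels:
//   G_y(f) = T(f) diag(Gu(f,)) T(f)^H + Gn(,,f)
// Gu: nf x nu one-sided input spectral densities; Gn: real nc x nc x nf
// measurement-noise cross-spectra.  Output is Hermitian by construction.
//
// The state space has second-order structure, x = (v, z) with dv/dt = z,
// so the resolvent reduces by Schur complement to an (n/2)-dimensional
// solve: with A(w) = [[0, I], [K(w), D]] (D diagonal), observation on v
// and input on z,
//   v = S(w)^-1 b_z,  S(w) = -K(w) - w^2 I - i w D.
// [[Rcpp::export]]
arma::cx_cube cmc_csd_cpp(const arma::mat& A0, const arma::mat& Ai,
                          const arma::mat& Ae, const arma::mat& B,
                          const arma::mat& L, double tau_i, double tau_e,
                          const arma::vec& freq, const arma::mat& Gu,
                          const arma::cube& Gn, bool guard = false) {
  const uword n = A0.n_rows, np = n / 2, nc = L.n_rows, nf = freq.n_elem;
  if (guard) {
    // stability of the zero-delay system matrix (delays only add phase)
    cx_vec ev = eig_gen(A0 + Ai + Ae);
    if (max(real(ev)) >= 0.0) Rcpp::stop("unstable linearization");
  }
  mat K0 = A0.submat(np, 0, n - 1, np - 1);
  mat Ki = Ai.submat(np, 0, n - 1, np - 1);
  mat Ke = Ae.submat(np, 0, n - 1, np - 1);
  vec d = A0.submat(np, np, n - 1, n - 1).diag();   // -2 kappa
  mat Bz = B.rows(np, n - 1);
  mat Lv = L.cols(0, np - 1);
  cx_mat Bzc = conv_to<cx_mat>::from(Bz), Lvc = conv_to<cx_mat>::from(Lv);
  cx_mat K0c = conv_to<cx_mat>::from(K0), Kic = conv_to<cx_mat>::from(Ki),
         Kec = conv_to<cx_mat>::from(Ke);
  cx_vec dc = conv_to<cx_vec>::from(d);
  cx_mat S(np, np), V;
  cx_cube out(nc, nc, nf);
  for (uword k = 0; k < nf; ++k) {
    double w = 2.0 * datum::pi * freq(k);
    std::complex<double> ei = std::exp(std::complex<double>(0.0, -w * tau_i));
    std::complex<double> ee = std::exp(std::complex<double>(0.0, -w * tau_e));
    S = -ei * Kic - ee * Kec - K0c;
    S.diag() -= w * w;
    S.diag() -= std::complex<double>(0.0, w) * dc;
    bool ok = solve(V, S, Bzc, solve_opts::no_approx);
    if (!ok) Rcpp::stop("singular resolvent at frequency %f Hz", freq(k));
    cx_mat Tk = Lvc * V;
    cx_mat G = Tk * diagmat(conv_to<cx_vec>::from(Gu.row(k).t())) * Tk.t();
    G += conv_to<cx_mat>::from(Gn.slice(k));
    out.slice(k) = 0.5 * (G + G.t());  // enforce exact Hermitian symmetry
  }
  return out;
}

static inline double sig(double v, double gamma) {
  return 1.0 / (1.0 + std::exp(-gamma * v)) - 0.5;
}

// Linear interpolation of the depolarisation history at time index td (in
// units of dt, may be fractional); history column 0 is t = 0, and times
// before 0 return the initial condition.
static inline void vlookup(const mat& vhist, double td, vec& out) {
  if (td <= 0.0) { out = vhist.col(0); return; }
  uword i0 = (uword)std::floor(td);
  double fr = td - (double)i0;
  if (fr < 1e-12) { out = vhist.col(i0); return; }
  out = (1.0 - fr) * vhist.col(i0) + fr * vhist.col(i0 + 1);
}

// Derivatives of the second-order synaptic dynamics, given current (v, z),
// delayed depolarisations per delay group and the exogenous drive.
static void cmc_deriv(const vec& v, const vec& z, const vec& vdi,
                      const vec& vde, const vec& u, const vec& kappa,
                      const mat& edges, double gamma, const vec& dw,
                      const ivec& dcol, vec& dv, vec& dz) {
  const uword np = kappa.n_elem, ne = edges.n_rows;
  dv = z;
  vec inp(np, fill::zeros);
  for (uword e = 0; e < ne; ++e) {
    uword tgt = (uword)edges(e, 0), src = (uword)edges(e, 1);
    double w = edges(e, 2);
    const vec& vd = (edges(e, 3) > 0.5) ? vde : vdi;
    inp(tgt) += w * sig(vd(src), gamma);
  }
  for (uword p = 0; p < np; ++p) {
    double drv = (dcol(p) >= 0) ? dw(p) * u((uword)dcol(p)) : 0.0;
    dz(p) = kappa(p) * (inp(p) + drv) - 2.0 * kappa(p) * z(p)
            - kappa(p) * kappa(p) * v(p);
  }
}

// Fixed-step RK4 integration of the delay differential equations.
//   kappa  : per-population synaptic rate constants (1/s)
//   edges  : rows (target_pop, source_pop, weight_Hz, delay_group) 0-based,
//            delay_group 0 = intrinsic, 1 = extrinsic
//   drive  : (nsteps+1) x n_inputs exogenous drive sampled on the time grid
//   dw     : per-population drive weight; dcol: 0-based drive column or -1
//   init   : initial state (v_1..v_np, z_1..z_np)
// Returns the full state (2 np rows) thinned by keep_every (column 0 = t 0).
// [[Rcpp::export]]
arma::mat cmc_integrate_cpp(const arma::vec& kappa, const arma::mat& edges,
                            double gamma, double tau_i, double tau_e,
                            const arma::mat& drive, const arma::vec& dw,
                            const arma::ivec& dcol, double dt,
                            const arma::vec& init, int keep_every) {
  const uword np = kappa.n_elem;
  const uword nsteps = drive.n_rows - 1;
  if (dt <= 0.0) Rcpp::stop("dt must be positive");
  if (dt > tau_i || dt > tau_e)
    Rcpp::stop("dt must not exceed the smallest conduction delay");

  vec v = init.subvec(0, np - 1), z = init.subvec(np, 2 * np - 1);
  mat vhist(np, nsteps + 1);
  vhist.col(0) = v;

  const uword nkeep = nsteps / keep_every + 1;
  mat out(2 * np, nkeep);
  out.col(0) = init;
  uword kept = 1;

  vec k1v(np), k1z(np), k2v(np), k2z(np), k3v(np), k3z(np), k4v(np), k4z(np);
  vec vdi(np), vde(np), vdi2(np), vde2(np), vdi3(np), vde3(np);
  vec u0(drive.n_cols), uh(drive.n_cols), u1(drive.n_cols);
  const double di = tau_i / dt, de = tau_e / dt;

  for (uword s = 0; s < nsteps; ++s) {
    double ts = (double)s;
    u0 = drive.row(s).t();
    u1 = drive.row(s + 1).t();
    uh = 0.5 * (u0 + u1);
    // delayed states for the three stage times t, t + dt/2, t + dt
    vlookup(vhist, ts - di, vdi);
    vlookup(vhist, ts - de, vde);
    vlookup(vhist, ts + 0.5 - di, vdi2);
    vlookup(vhist, ts + 0.5 - de, vde2);
    vlookup(vhist, ts + 1.0 - di, vdi3);
    vlookup(vhist, ts + 1.0 - de, vde3);

    cmc_deriv(v, z, vdi, vde, u0, kappa, edges, gamma, dw, dcol, k1v, k1z);
    cmc_deriv(v + 0.5 * dt * k1v, z + 0.5 * dt * k1z, vdi2, vde2, uh,
              kappa, edges, gamma, dw, dcol, k2v, k2z);
    cmc_deriv(v + 0.5 * dt * k2v, z + 0.5 * dt * k2z, vdi2, vde2, uh,
              kappa, edges, gamma, dw, dcol, k3v, k3z);
    cmc_deriv(v + dt * k3v, z + dt * k3z, vdi3, vde3, u1,
              kappa, edges, gamma, dw, dcol, k4v, k4z);

    v += (dt / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    z += (dt / 6.0) * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
    if (!v.is_finite() || !z.is_finite())
      Rcpp::stop("state diverged (non-finite) at step %d (t = %f s)",
                 (int)(s + 1), (s + 1) * dt);
    vhist.col(s + 1) = v;
    if ((s + 1) % (uword)keep_every == 0 && kept < nkeep) {
      out.col(kept).subvec(0, np - 1) = v;
      out.col(kept).subvec(np, 2 * np - 1) = z;
      ++kept;
    }
  }
  return out;
}
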