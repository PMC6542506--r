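// Core numerics for the excitatory-inhibitory neural population model:
// ODE right-hand side, equilibrium search, analytic Jacobian, transfer-gain
// spectrum and Euler-Maruyama simulation.  All computation is in mV and ms;
// frequencies arrive in Hz and are converted as omega = 2*pi*f/1000 rad/ms.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EULER_E = 2.718281828459045235;

// Parameter vector order (fixed across the package):
//  0 h_e_rest  1 h_i_rest  2 h_e_eq   3 h_i_eq
//  4 S_e_max   5 S_i_max   6 mu_e     7 mu_i
//  8 sigma_e   9 sigma_i  10 tau_e   11 tau_i
// 12 gamma_e  13 gamma_i  14 Gamma_e 15 Gamma_i
// 16 p_ee     17 p_ei     18 N_ee    19 N_ie    20 N_ei    21 N_ii
struct Pars {
  double her, hir, hee, hie;
  double Sem, Sim, mue, mui, sge, sgi;
  double te, ti, ge, gi, Ge, Gi;
  double pee, pei, Nee, Nie, Nei, Nii;
  double pie, pii;          // fixed external inhibitory inputs
  double sc;                // sigmoid exponent scale (default sqrt(2))
  double Dee, Die, Dei, Dii; // weighting denominators |h_eq - h_rest|
};

static Pars unpack(const arma::vec& th, double sc) {
  Pars p;
  p.her = th(0);  p.hir = th(1);  p.hee = th(2);  p.hie = th(3);
  p.Sem = th(4);  p.Sim = th(5);  p.mue = th(6);  p.mui = th(7);
  p.sge = th(8);  p.sgi = th(9);  p.te  = th(10); p.ti  = th(11);
  p.ge  = th(12); p.gi  = th(13); p.Ge  = th(14); p.Gi  = th(15);
  p.pee = th(16); p.pei = th(17); p.Nee = th(18); p.Nie = th(19);
  p.Nei = th(20); p.Nii = th(21);
  p.pie = 0.0; p.pii = 0.0;
  p.sc  = sc;
  p.Dee = std::abs(p.hee - p.her);
  p.Die = std::abs(p.hie - p.her);
  p.Dei = std::abs(p.hee - p.hir);
  p.Dii = std::abs(p.hie - p.hir);
  return p;
}

static inline double sigm(double h, double Smax, double mu, double sg, double sc) {
  return Smax / (1.0 + std::exp(-sc * (h - mu) / sg));
}
static inline double dsigm(double h, double Smax, double mu, double sg, double sc) {
  double s = sigm(h, Smax, mu, sg, sc);
  return (sc / sg) * s * (1.0 - s / Smax);
}

// State order: h_e, h_i, I_ee, dI_ee, I_ie, dI_ie, I_ei, dI_ei, I_ii, dI_ii
static arma::vec rhs_(const Pars& p, const arma::vec& x) {
  arma::vec f(10);
  double he = x(0), hi = x(1);
  double Se = sigm(he, p.Sem, p.mue, p.sge, p.sc);
  double Si = sigm(hi, p.Sim, p.mui, p.sgi, p.sc);
  double wee = (p.hee - he) / p.Dee, wie = (p.hie - he) / p.Die;
  double wei = (p.hee - hi) / p.Dei, wii = (p.hie - hi) / p.Dii;
  f(0) = (p.her - he + wee * x(2) + wie * x(4)) / p.te;
  f(1) = (p.hir - hi + wei * x(6) + wii * x(8)) / p.ti;
  f(2) = x(3);
  f(3) = -2.0 * p.ge * x(3) - p.ge * p.ge * x(2) +
         p.Ge * p.ge * EULER_E * (p.Nee * Se + p.pee);
  f(4) = x(5);
  f(5) = -2.0 * p.gi * x(5) - p.gi * p.gi * x(4) +
         p.Gi * p.gi * EULER_E * (p.Nie * Si + p.pie);
  f(6) = x(7);
  f(7) = -2.0 * p.ge * x(7) - p.ge * p.ge * x(6) +
         p.Ge * p.ge * EULER_E * (p.Nei * Se + p.pei);
  f(8) = x(9);
  f(9) = -2.0 * p.gi * x(9) - p.gi * p.gi * x(8) +
         p.Gi * p.gi * EULER_E * (p.Nii * Si + p.pii);
  return f;
}

static arma::mat jac_(const Pars& p, const arma::vec& x) {
  arma::mat A(10, 10, arma::fill::zeros);
  double he = x(0), hi = x(1);
  double wee = (p.hee - he) / p.Dee, wie = (p.hie - he) / p.Die;
  double wei = (p.hee - hi) / p.Dei, wii = (p.hie - hi) / p.Dii;
  double dSe = dsigm(he, p.Sem, p.mue, p.sge, p.sc);
  double dSi = dsigm(hi, p.Sim, p.mui, p.sgi, p.sc);
  A(0, 0) = (-1.0 - x(2) / p.Dee - x(4) / p.Die) / p.te;
  A(0, 2) = wee / p.te;
  A(0, 4) = wie / p.te;
  A(1, 1) = (-1.0 - x(6) / p.Dei - x(8) / p.Dii) / p.ti;
  A(1, 6) = wei / p.ti;
  A(1, 8) = wii / p.ti;
  A(2, 3) = 1.0;
  A(3, 0) = p.Ge * p.ge * EULER_E * p.Nee * dSe;
  A(3, 2) = -p.ge * p.ge;  A(3, 3) = -2.0 * p.ge;
  A(4, 5) = 1.0;
  A(5, 1) = p.Gi * p.gi * EULER_E * p.Nie * dSi;
  A(5, 4) = -p.gi * p.gi;  A(5, 5) = -2.0 * p.gi;
  A(6, 7) = 1.0;
  A(7, 0) = p.Ge * p.ge * EULER_E * p.Nei * dSe;
  A(7, 6) = -p.ge * p.ge;  A(7, 7) = -2.0 * p.ge;
  A(8, 9) = 1.0;
  A(9, 1) = p.Gi * p.gi * EULER_E * p.Nii * dSi;
  A(9, 8) = -p.gi * p.gi;  A(9, 9) = -2.0 * p.gi;
  return A;
}

// Steady-state synaptic activities given the membrane potentials
static inline void Istar(const Pars& p, double he, double hi, double I[4]) {
  double Se = sigm(he, p.Sem, p.mue, p.sge, p.sc);
  double Si = sigm(hi, p.Sim, p.mui, p.sgi, p.sc);
  I[0] = (p.Ge * EULER_E / p.ge) * (p.Nee * Se + p.pee); // I_ee
  I[1] = (p.Gi * EULER_E / p.gi) * (p.Nie * Si + p.pie); // I_ie
  I[2] = (p.Ge * EULER_E / p.ge) * (p.Nei * Se + p.pei); // I_ei
  I[3] = (p.Gi * EULER_E / p.gi) * (p.Nii * Si + p.pii); // I_ii
}

// 2-d reduced steady-state residual (the tau*dh/dt equations) and its Jacobian
static void F2d(const Pars& p, double he, double hi, double F[2], double J[4]) {
  double I[4];
  Istar(p, he, hi, I);
  double wee = (p.hee - he) / p.Dee, wie = (p.hie - he) / p.Die;
  double wei = (p.hee - hi) / p.Dei, wii = (p.hie - hi) / p.Dii;
  double dSe = dsigm(he, p.Sem, p.mue, p.sge, p.sc);
  double dSi = dsigm(hi, p.Sim, p.mui, p.sgi, p.sc);
  double dIee = (p.Ge * EULER_E / p.ge) * p.Nee * dSe;
  double dIie = (p.Gi * EULER_E / p.gi) * p.Nie * dSi;
  double dIei = (p.Ge * EULER_E / p.ge) * p.Nei * dSe;
  double dIii = (p.Gi * EULER_E / p.gi) * p.Nii * dSi;
  F[0] = p.her - he + wee * I[0] + wie * I[1];
  F[1] = p.hir - hi + wei * I[2] + wii * I[3];
  J[0] = -1.0 - I[0] / p.Dee - I[1] / p.Die + wee * dIee;  // dF1/dhe
  J[1] = wie * dIie;                                       // dF1/dhi
  J[2] = wei * dIei;                                       // dF2/dhe
  J[3] = -1.0 - I[2] / p.Dei - I[3] / p.Dii + wii * dIii;  // dF2/dhi
}

// Damped Newton from one start.  Returns 1 on convergence to a new root,
// 2 if the iterate lands within dedupe distance of an already-found root
// (start abandoned early), 0 on failure.
static int newton2d(const Pars& p, double& he, double& hi, double tol, int maxit,
                    const std::vector<double>& rhe, const std::vector<double>& rhi) {
  double F[2], J[4];
  F2d(p, he, hi, F, J);
  for (int it = 0; it < maxit; ++it) {
    for (size_t k = 0; k < rhe.size(); ++k)
      if (std::abs(rhe[k] - he) < 1e-6 && std::abs(rhi[k] - hi) < 1e-6)
        return 2;
    double nrm = std::max(std::abs(F[0]), std::abs(F[1]));
    if (nrm < tol) return 1;
    double det = J[0] * J[3] - J[1] * J[2];
    if (std::abs(det) < 1e-300) return 0;
    double dhe = -(J[3] * F[0] - J[1] * F[1]) / det;
    double dhi = -(-J[2] * F[0] + J[0] * F[1]) / det;
    // damping: backtrack until the residual shrinks
    double lam = 1.0;
    bool moved = false;
    for (int k = 0; k < 10; ++k) {
      double he2 = he + lam * dhe, hi2 = hi + lam * dhi;
      double Ft[2], Jt[4];
      F2d(p, he2, hi2, Ft, Jt);
      if (std::max(std::abs(Ft[0]), std::abs(Ft[1])) < nrm) {
        he = he2; hi = hi2;
        F[0] = Ft[0]; F[1] = Ft[1];
        J[0] = Jt[0]; J[1] = Jt[1]; J[2] = Jt[2]; J[3] = Jt[3];
        moved = true;
        break;
      }
      lam *= 0.5;
    }
    if (!moved) return 0;  // stuck on a residual plateau: not a root basin
    if (!std::isfinite(he) || !std::isfinite(hi)) return 0;
    if (he < -300.0 || he > 200.0 || hi < -300.0 || hi > 200.0) return 0;
  }
  return 0;
}

static arma::vec full_state(const Pars& p, double he, double hi) {
  double I[4];
  Istar(p, he, hi, I);
  arma::vec x(10, arma::fill::zeros);
  x(0) = he; x(1) = hi;
  x(2) = I[0]; x(4) = I[1]; x(6) = I[2]; x(8) = I[3];
  return x;
}

// Multi-start equilibrium search over a grid in (h_e, h_i).
// Returns deduplicated roots with stability information.
// [[Rcpp::export]]
List cpp_equilibria(const arma::vec& theta, double sc,
                    int grid_n = 12, double lo = -90.0, double hi_ = -10.0,
                    double tol = 1e-12) {
  Pars p = unpack(theta, sc);
  std::vector<double> rhe, rhi;
  for (int i = 0; i < grid_n; ++i) {
    for (int j = 0; j < grid_n; ++j) {
      double he = lo + (hi_ - lo) * (i + 0.5) / grid_n;
      double hv = lo + (hi_ - lo) * (j + 0.5) / grid_n;
      if (newton2d(p, he, hv, tol, 80, rhe, rhi) != 1) continue;
      bool dup = false;
      for (size_t k = 0; k < rhe.size(); ++k)
        if (std::abs(rhe[k] - he) < 1e-6 && std::abs(rhi[k] - hv) < 1e-6) { dup = true; break; }
      if (!dup) { rhe.push_back(he); rhi.push_back(hv); }
    }
  }
  int nr = rhe.size();
  arma::mat roots(nr, 2);
  arma::mat Imat(nr, 4);
  LogicalVector stable(nr);
  NumericVector maxre(nr);
  NumericVector resid(nr);
  for (int k = 0; k < nr; ++k) {
    roots(k, 0) = rhe[k]; roots(k, 1) = rhi[k];
    arma::vec x = full_state(p, rhe[k], rhi[k]);
    Imat(k, 0) = x(2); Imat(k, 1) = x(4); Imat(k, 2) = x(6); Imat(k, 3) = x(8);
    arma::cx_vec ev;
    arma::mat A = jac_(p, x);
    bool ok = arma::eig_gen(ev, A);
    double mr = ok ? arma::max(arma::real(ev)) : NA_REAL;
    maxre[k] = mr;
    stable[k] = ok && (mr < 0.0);
    resid[k] = arma::abs(rhs_(p, x)).max();
  }
  return List::create(_["roots"] = roots, _["I"] = Imat,
                      _["stable"] = stable, _["max_re"] = maxre,
                      _["residual"] = resid);
}

// [[Rcpp::export]]
arma::vec cpp_rhs(const arma::vec& theta, const arma::vec& state, double sc) {
  return rhs_(unpack(theta, sc), state);
}

// [[Rcpp::export]]
arma::mat cpp_jacobian(const arma::vec& theta, const arma::vec& state, double sc) {
  return jac_(unpack(theta, sc), state);
}

// |C (i w I - A)^-1 B|^2 at each frequency (Hz); internal unit rad/ms
// [[Rcpp::export]]
arma::vec cpp_tf_gain(const arma::mat& A, const arma::vec& B,
                      const arma::vec& Cv, const arma::vec& freqs) {
  int n = A.n_rows;
  arma::cx_mat Ac = arma::cx_mat(A, arma::mat(n, n, arma::fill::zeros));
  arma::cx_vec Bc = arma::cx_vec(B, arma::vec(n, arma::fill::zeros));
  arma::vec out(freqs.n_elem);
  for (arma::uword k = 0; k < freqs.n_elem; ++k) {
    double w = 2.0 * M_PI * freqs(k) / 1000.0;
    arma::cx_mat M = arma::cx_mat(arma::mat(n, n, arma::fill::zeros),
                                  w * arma::eye(n, n)) - Ac;
    arma::cx_vec x;
    bool ok = arma::solve(x, M, Bc);
    if (!ok) { out(k) = arma::datum::nan; continue; }
    std::complex<double> g(0.0, 0.0);
    for (int i = 0; i < n; ++i) g += Cv(i) * x(i);
    out(k) = std::norm(g);
  }
  return out;
}

// Closed-form transfer gain exploiting the block structure of the Jacobian.
// Eliminating the four second-order synaptic blocks (all sharing the two
// double poles (s+gamma_e)^2, (s+gamma_i)^2) reduces the p_ee -> h_e
// transfer function to a scalar rational expression: the excitatory membrane
// line closed by the e->e synaptic loop and by the e->i->e branch, the
// latter itself closed by the i->i loop.  Mathematically identical to
// C (i w I - A)^-1 B with the full 10-d state space (asserted against that
// route in the test suite), but O(1) complex arithmetic per frequency.
static arma::vec tf_gain_closed(const Pars& p, const arma::vec& x,
                                const arma::vec& freqs) {
  arma::mat A = jac_(p, x);
  const double g0 = p.Ge * p.ge * EULER_E;
  arma::vec out(freqs.n_elem);
  for (arma::uword k = 0; k < freqs.n_elem; ++k) {
    std::complex<double> s(0.0, 2.0 * M_PI * freqs(k) / 1000.0);
    std::complex<double> Le = (s + p.ge) * (s + p.ge);
    std::complex<double> Li = (s + p.gi) * (s + p.gi);
    std::complex<double> Di = (s - A(1, 1)) - A(1, 8) * A(9, 1) / Li;
    std::complex<double> den = (s - A(0, 0)) - A(0, 2) * A(3, 0) / Le -
      A(0, 4) * A(5, 1) * A(1, 6) * A(7, 0) / (Le * Li * Di);
    out(k) = std::norm((A(0, 2) * g0 / Le) / den);
  }
  return out;
}

// Full pipeline for one physical parameter vector: equilibrium selection,
// stability check, model spectrum.  status: 0 ok, 1 no stable equilibrium,
// 2 no equilibrium found.
// [[Rcpp::export]]
List cpp_spectrum(const arma::vec& theta, const arma::vec& freqs, double sc) {
  List eqs = cpp_equilibria(theta, sc);
  arma::mat roots = eqs["roots"];
  LogicalVector stable = eqs["stable"];
  int nr = roots.n_rows;
  if (nr == 0) return List::create(_["status"] = 2);
  int best = -1;
  int n_stable = 0;
  for (int k = 0; k < nr; ++k) {
    if (stable[k]) {
      ++n_stable;
      if (best < 0 || roots(k, 0) < roots(best, 0)) best = k;
    }
  }
  if (best < 0) return List::create(_["status"] = 1);
  Pars p = unpack(theta, sc);
  arma::vec x = full_state(p, roots(best, 0), roots(best, 1));
  arma::vec S = tf_gain_closed(p, x, freqs);
  return List::create(_["status"] = 0, _["S"] = S,
                      _["h_e"] = roots(best, 0), _["h_i"] = roots(best, 1),
                      _["n_stable"] = n_stable);
}

// Euler-Maruyama integration with white noise on p_ee.  Noise of standard
// deviation noise_sd (rate units, 1/ms) enters the dI_ee/dt equation scaled by
// Gamma_e*gamma_e*e, matching a perturbation of the external drive p_ee.
// Uses R's RNG so results are reproducible via set.seed().
// mode 0 = full nonlinear equations, 1 = linearization about the equilibrium.
// [[Rcpp::export]]
List cpp_simulate(const arma::vec& theta, double sc,
                  const arma::vec& xinit, const arma::vec& xeq,
                  const arma::mat& A, int mode,
                  int n_out, int substeps, double dt, double noise_sd) {
  Pars p = unpack(theta, sc);
  arma::vec x = xinit;
  arma::vec out(n_out);
  double amp = p.Ge * p.ge * EULER_E * noise_sd * std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n_out; ++i) {
    for (int s = 0; s < substeps; ++s) {
      arma::vec f = (mode == 0) ? rhs_(p, x) : arma::vec(A * (x - xeq));
      x += dt * f;
      if (noise_sd > 0.0) x(3) += amp * norm_rand();
    }
    double he = x(0);
    if (!std::isfinite(he) || he > 0.0)
      return List::create(_["status"] = 1, _["h_e"] = out, _["i"] = i);
    out(i) = he;
  }
  return List::create(_["status"] = 0, _["h_e"] = out);
}
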