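// [[Rcpp::depends(RcppArmadillo)]]
#include "confold.h"
using namespace arma;

// Three-gradient contact restraint: flat well (-U) below 8 A, strong
// sinusoidal rise to D = 8 + db, weak sinusoidal rise to 80 A, flat (+U)
// beyond. Continuous with zero slope at 8, D and 80.
double econ_core(double d, double U, double db) {
  double D = 8.0 + db;
  if (d < 8.0) return -U;
  if (d < D)
    return -0.5 * U * (1.0 - std::sin((d - 0.5 * (8.0 + D)) / db * M_PI));
  if (d <= 80.0)
    return 0.5 * U * (1.0 + std::sin((d - 0.5 * (D + 80.0)) / (80.0 - D) * M_PI));
  return U;
}

EModel model_from_list(const Rcpp::List &m) {
  EModel e;
  e.L = Rcpp::as<int>(m["L"]);
  e.rest = Rcpp::as<imat>(m["rest"]);
  e.restU = Rcpp::as<vec>(m["restU"]);
  e.ppairs = Rcpp::as<imat>(m["ppairs"]);
  e.ptab = Rcpp::as<mat>(m["ptab"]);
  e.nbin = e.ptab.n_cols > 0 ? (int)e.ptab.n_cols : 80;
  vec w = Rcpp::as<vec>(m["weights"]);
  e.w_con = w(0); e.w_dp = w(1); e.w_ca = w(2);
  e.w_ev = w(3); e.w_ss = w(4); e.w_rg = w(5);
  e.db = Rcpp::as<double>(m["db"]);
  e.is_gly = Rcpp::as<ivec>(m["is_gly"]);
  e.ss = Rcpp::as<ivec>(m["ss"]);
  e.ss_w = Rcpp::as<vec>(m["ss_w"]);
  vec th0 = Rcpp::as<vec>(m["theta0"]), ta0 = Rcpp::as<vec>(m["tau0"]);
  for (int k = 0; k < 3; k++) { e.theta0[k] = th0(k); e.tau0[k] = ta0(k); }
  e.rg0 = Rcpp::as<double>(m["rg0"]);
  return e;
}

static inline double dist_rows(const mat &x, int i, int j) {
  return norm(x.row(i) - x.row(j));
}

static inline double edp_pair(const mat &ca, const EModel &m, int k) {
  double d = dist_rows(ca, m.ppairs(k, 0), m.ppairs(k, 1));
  int b = (int)(d / 0.5);
  if (b < 0 || b >= m.nbin) return 0.0;
  return m.ptab(k, b);
}

static inline double eca_bond(const mat &ca, int i) {
  double d = dist_rows(ca, i, i + 1);
  return d > 4.0 ? (d - 4.0) * (d - 4.0) : 0.0;
}

static inline double eev_pair(const mat &ca, int i, int j) {
  double d = dist_rows(ca, i, j);
  return d < 3.6 ? (3.6 - d) * (3.6 - d) : 0.0;
}

// SS bias for residue i: quadratic in the pseudo bond angle plus a smooth
// 1-cos torsion restraint toward the state's ideal values.
static double ess_res(const mat &ca, const EModel &m, int i) {
  int L = ca.n_rows;
  if (m.ss_w(i) <= 0.0) return 0.0;
  int st = m.ss(i);
  double e = 0.0;
  if (i >= 1 && i <= L - 2) {
    double dth = pseudo_theta(ca, i) - m.theta0[st];
    e += m.ss_w(i) * dth * dth;
  }
  if (i >= 1 && i <= L - 3)
    e += m.ss_w(i) * (1.0 - std::cos(pseudo_tau(ca, i) - m.tau0[st]));
  return e;
}

static double erg_term(const mat &ca, const EModel &m) {
  rowvec c = mean(ca, 0);
  double rg = std::sqrt(accu(square(ca.each_row() - c)) / ca.n_rows);
  double lo = 0.85 * m.rg0, hi = 1.15 * m.rg0;
  if (rg < lo) return (lo - rg) * (lo - rg);
  if (rg > hi) return (rg - hi) * (rg - hi);
  return 0.0;
}

// Weighted per-term energies: (con, dp, ca, ev, ss, rg).
vec energy_terms(const mat &ca, const mat &cb, const EModel &m) {
  int L = m.L;
  vec out(6, fill::zeros);
  for (unsigned k = 0; k < m.rest.n_rows; k++)
    out(0) += econ_core(dist_rows(cb, m.rest(k, 0), m.rest(k, 1)), m.restU(k), m.db);
  for (unsigned k = 0; k < m.ppairs.n_rows; k++)
    out(1) += edp_pair(ca, m, k);
  for (int i = 0; i < L - 1; i++) out(2) += eca_bond(ca, i);
  for (int i = 0; i < L - 2; i++)
    for (int j = i + 2; j < L; j++) out(3) += eev_pair(ca, i, j);
  for (int i = 0; i < L; i++) out(4) += ess_res(ca, m, i);
  out(5) = erg_term(ca, m);
  out(0) *= m.w_con; out(1) *= m.w_dp; out(2) *= m.w_ca;
  out(3) *= m.w_ev; out(4) *= m.w_ss; out(5) *= m.w_rg;
  return out;
}

double energy_total(const mat &ca, const mat &cb, const EModel &m) {
  return accu(energy_terms(ca, cb, m));
}

// Energy restricted to interactions touching residues [a, b] (after expanding
// for the C-beta and pseudo-angle stencils). The radius-of-gyration term is
// global and is always included in full.
static double energy_touching(const mat &ca, const mat &cb, const EModel &m,
                              int a, int b) {
  int L = m.L;
  int alo = std::max(0, a - 1), bhi = std::min(L - 1, b + 1);  // C-beta stencil
  double e_con = 0.0, e_dp = 0.0, e_ca = 0.0, e_ev = 0.0, e_ss = 0.0;
  for (unsigned k = 0; k < m.rest.n_rows; k++) {
    int i = m.rest(k, 0), j = m.rest(k, 1);
    if ((i >= alo && i <= bhi) || (j >= alo && j <= bhi))
      e_con += econ_core(dist_rows(cb, i, j), m.restU(k), m.db);
  }
  for (unsigned k = 0; k < m.ppairs.n_rows; k++) {
    int i = m.ppairs(k, 0), j = m.ppairs(k, 1);
    if ((i >= a && i <= b) || (j >= a && j <= b)) e_dp += edp_pair(ca, m, k);
  }
  for (int i = std::max(0, a - 1); i <= std::min(L - 2, b); i++)
    e_ca += eca_bond(ca, i);
  for (int i = a; i <= b; i++)
    for (int j = 0; j < L; j++) {
      if (std::abs(i - j) < 2) continue;
      if (j >= a && j <= b && j < i) continue;  // count in-range pairs once
      e_ev += eev_pair(ca, std::min(i, j), std::max(i, j));
    }
  for (int i = std::max(0, a - 2); i <= std::min(L - 1, b + 2); i++)
    e_ss += ess_res(ca, m, i);
  return m.w_con * e_con + m.w_dp * e_dp + m.w_ca * e_ca +
         m.w_ev * e_ev + m.w_ss * e_ss + m.w_rg * erg_term(ca, m);
}

double energy_delta_range(const mat &ca0, const mat &cb0,
                          const mat &ca1, const mat &cb1,
                          int a, int b, const EModel &m) {
  return energy_touching(ca1, cb1, m, a, b) - energy_touching(ca0, cb0, m, a, b);
}

// [[Rcpp::export(name = "cpp_econ")]]
arma::vec cpp_econ(const arma::vec &d, double U, double db) {
  vec out(d.n_elem);
  for (unsigned i = 0; i < d.n_elem; i++) out(i) = econ_core(d(i), U, db);
  return out;
}

// [[Rcpp::export(name = "cpp_energy_terms")]]
arma::vec cpp_energy_terms(const arma::mat &ca, const Rcpp::List &model) {
  EModel m = model_from_list(model);
  mat cb = cbeta_coords(ca, m.is_gly);
  return energy_terms(ca, cb, m);
}

// [[Rcpp::export(name = "cpp_energy_delta")]]
double cpp_energy_delta(const arma::mat &ca0, const arma::mat &ca1,
                        int a, int b, const Rcpp::List &model) {
  EModel m = model_from_list(model);
  mat cb0 = cbeta_coords(ca0, m.is_gly);
  mat cb1 = cbeta_coords(ca1, m.is_gly);
  return energy_delta_range(ca0, cb0, ca1, cb1, a, b, m);
}
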