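// [[Rcpp::depends(RcppArmadillo)]]
#include "confold.h"
using namespace arma;

// Virtual C-beta from three consecutive C-alphas: 1.53 A from CA_i along the
// unit vector obtained by tilting the outward bisector of the (i-1, i, i+1)
// frame out of plane by 37.6 degrees. Chain termini and glycine fall back to
// the C-alpha position.
mat cbeta_coords(const mat &ca, const ivec &is_gly) {
  const double len = 1.53, elev = 37.6 * M_PI / 180.0;
  int L = ca.n_rows;
  mat cb = ca;
  for (int i = 1; i < L - 1; i++) {
    if (is_gly.n_elem == (unsigned)L && is_gly(i)) continue;
    rowvec u = ca.row(i - 1) - ca.row(i);
    rowvec v = ca.row(i + 1) - ca.row(i);
    double nu = norm(u), nv = norm(v);
    if (nu < 1e-9 || nv < 1e-9) continue;
    u /= nu; v /= nv;
    rowvec b = u + v;
    rowvec n = cross(u, v);
    double nb = norm(b), nn = norm(n);
    if (nb < 1e-6 || nn < 1e-6) continue;  // collinear: leave at C-alpha
    rowvec dir = -std::cos(elev) * (b / nb) + std::sin(elev) * (n / nn);
    cb.row(i) = ca.row(i) + len * dir;
  }
  return cb;
}

double pseudo_theta(const mat &ca, int i) {
  rowvec u = ca.row(i - 1) - ca.row(i);
  rowvec v = ca.row(i + 1) - ca.row(i);
  double c = dot(u, v) / (norm(u) * norm(v));
  c = std::max(-1.0, std::min(1.0, c));
  return std::acos(c);
}

double pseudo_tau(const mat &ca, int i) {
  rowvec b1 = ca.row(i) - ca.row(i - 1);
  rowvec b2 = ca.row(i + 1) - ca.row(i);
  rowvec b3 = ca.row(i + 2) - ca.row(i + 1);
  rowvec n1 = cross(b1, b2), n2 = cross(b2, b3);
  rowvec m1 = cross(n1, b2 / norm(b2));
  double xx = dot(n1, n2), yy = dot(m1, n2);
  return std::atan2(yy, xx);
}

// NeRF placement: position d such that |cd| = r, angle(b,c,d) = theta,
// dihedral(a,b,c,d) = tau.
rowvec place_nerf(const rowvec &a, const rowvec &b, const rowvec &c,
                  double r, double theta, double tau) {
  rowvec bc = c - b; bc /= norm(bc);
  rowvec ab = b - a;
  rowvec n = cross(ab, bc);
  double nn = norm(n);
  if (nn < 1e-9) {  // collinear history: pick any perpendicular
    rowvec t = {1, 0, 0};
    if (std::fabs(bc(0)) > 0.9) t = {0, 1, 0};
    n = cross(bc, t);
    nn = norm(n);
  }
  n /= nn;
  rowvec m = cross(n, bc);
  double ang = M_PI - theta;  // supplement: local x along bc
  // sign convention matches pseudo_tau: building with torsion t measures t
  rowvec d2 = {r * std::cos(ang), r * std::cos(tau) * std::sin(ang),
               -r * std::sin(tau) * std::sin(ang)};
  return c + d2(0) * bc + d2(1) * m + d2(2) * n;
}

// Rodrigues rotation of rows [from, to] about (origin, axis) by angle.
void rotate_range(mat &x, int from, int to, const rowvec &origin,
                  const rowvec &axis, double angle) {
  rowvec k = axis / norm(axis);
  double c = std::cos(angle), s = std::sin(angle);
  for (int i = from; i <= to; i++) {
    rowvec v = x.row(i) - origin;
    rowvec vr = v * c + cross(k, v) * s + k * dot(k, v) * (1 - c);
    x.row(i) = origin + vr;
  }
}

// Least-squares superposition of mobile onto ref (both n x 3) via SVD,
// with proper-rotation (determinant) correction.
static void kabsch_rt(const mat &mobile, const mat &ref, mat &R, rowvec &t) {
  rowvec cm = mean(mobile, 0), cr = mean(ref, 0);
  mat A = mobile.each_row() - cm;
  mat B = ref.each_row() - cr;
  mat H = A.t() * B;
  mat U, V; vec S;
  svd(U, S, V, H);
  double d = det(V * U.t());
  mat Dm = eye(3, 3);
  Dm(2, 2) = d < 0 ? -1.0 : 1.0;
  R = V * Dm * U.t();
  t = cr - cm * R.t();
}

mat kabsch_fit(const mat &mobile, const mat &ref) {
  mat R; rowvec t;
  kabsch_rt(mobile, ref, R, t);
  mat out = mobile * R.t();
  out.each_row() += t;
  return out;
}

double kabsch_rmsd_core(const mat &a, const mat &b) {
  mat af = kabsch_fit(a, b);
  return std::sqrt(accu(square(af - b)) / a.n_rows);
}

// [[Rcpp::export(name = "cpp_cbeta")]]
arma::mat cpp_cbeta(const arma::mat &ca, const arma::ivec &is_gly) {
  return cbeta_coords(ca, is_gly);
}

// [[Rcpp::export(name = "cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(const arma::mat &a, const arma::mat &b) {
  return kabsch_rmsd_core(a, b);
}

// [[Rcpp::export(name = "cpp_kabsch_fit")]]
arma::mat cpp_kabsch_fit(const arma::mat &mobile, const arma::mat &ref) {
  return kabsch_fit(mobile, ref);
}

// [[Rcpp::export(name = "cpp_pseudo_angles")]]
Rcpp::List cpp_pseudo_angles(const arma::mat &ca) {
  int L = ca.n_rows;
  vec theta(L); theta.fill(datum::nan);
  vec tau(L); tau.fill(datum::nan);
  for (int i = 1; i < L - 1; i++) theta(i) = pseudo_theta(ca, i);
  for (int i = 1; i < L - 2; i++) tau(i) = pseudo_tau(ca, i);
  return Rcpp::List::create(Rcpp::Named("theta") = theta, Rcpp::Named("tau") = tau);
}

// Build a chain from per-residue internal coordinates (bond fixed, theta(i)
// used at residue i as the angle for placing i+1, tau(i) as the dihedral for
// placing i+2). theta/tau are in radians; entries outside their valid range
// are ignored.
// [[Rcpp::export(name = "cpp_build_chain")]]
arma::mat cpp_build_chain(int L, const arma::vec &theta, const arma::vec &tau,
                          double bond) {
  mat x(L, 3, fill::zeros);
  if (L == 0) return x;
  x.row(0) = rowvec({0, 0, 0});
  if (L > 1) x.row(1) = rowvec({bond, 0, 0});
  if (L > 2) {
    double th = theta(1);
    x.row(2) = rowvec({bond - bond * std::cos(th), bond * std::sin(th), 0});
  }
  for (int i = 3; i < L; i++) {
    x.row(i) = place_nerf(x.row(i - 3), x.row(i - 2), x.row(i - 1),
                          bond, theta(i - 1), tau(i - 2));
  }
  return x;
}

// RMSD matrix over a stack of conformations (n x (L*3), row-major per decoy).
// [[Rcpp::export(name = "cpp_rmsd_matrix")]]
arma::mat cpp_rmsd_matrix(const arma::mat &stack, int L) {
  int n = stack.n_rows;
  mat D(n, n, fill::zeros);
  std::vector<mat> xs(n);
  for (int i = 0; i < n; i++)
    xs[i] = reshape(stack.row(i), 3, L).t();
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double r = kabsch_rmsd_core(xs[i], xs[j]);
      D(i, j) = r; D(j, i) = r;
    }
  return D;
}

// TM-score by iterative superposition from multiple window seeds.
// d0 is supplied by the caller (R side owns the normalisation rule).
// [[Rcpp::export(name = "cpp_tm_score")]]
double cpp_tm_score(const arma::mat &model, const arma::mat &native, double d0) {
  int L = model.n_rows;
  double d02 = d0 * d0;
  // exhaustive window seeding: every contiguous window of every length >= 4
  std::vector<int> lens;
  for (int l = 4; l <= L; l++) lens.push_back(l);
  double best = 0.0;
  for (int l : lens) {
    for (int s = 0; s + l <= L; s++) {
      uvec idx = regspace<uvec>(s, s + l - 1);
      for (int iter = 0; iter < 24; iter++) {
        mat R; rowvec t;
        kabsch_rt(model.rows(idx), native.rows(idx), R, t);
        mat mfit = model * R.t();
        mfit.each_row() += t;
        vec d2 = sum(square(mfit - native), 1);
        double sc = accu(1.0 / (1.0 + d2 / d02)) / L;
        if (sc > best) best = sc;
        double dcut = d0;
        uvec nidx = find(d2 < dcut * dcut);
        while (nidx.n_elem < 4 && dcut < 50.0) {
          dcut += 0.5;
          nidx = find(d2 < dcut * dcut);
        }
        if (nidx.n_elem == idx.n_elem && accu(nidx != idx) == 0) break;
        idx = nidx;
        if (idx.n_elem < 3) break;
      }
    }
  }
  return best;
}
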