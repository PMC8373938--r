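// [[Rcpp::depends(RcppArmadillo)]]
#include "confold.h"
using namespace arma;

// Conformational move set in three levels:
//   residue   M1 torsion perturbation, M2 local displacement, M3 bond-angle
//             perturbation, M4 reset of one residue to its SS-ideal angles
//   segmental M5 fragment substitution, M6 crankshaft, M7 segment shift,
//             M8 loop re-draw with rigid downstream re-attachment
//   topology  M9 terminal-tail hinge rotation, M10 rigid SSE translation,
//             M11 rigid SSE rotation about its own axis
// Every move either returns a proposal whose adjacent C-alpha distances stay
// inside [3.4, 4.2] A or fails (flagged rejection, structure unchanged).

static const double BOND_LO = 3.4, BOND_HI = 4.2;

static bool bond_ok(const mat &x, int i, int j) {
  double d = norm(x.row(i) - x.row(j));
  return d >= BOND_LO && d <= BOND_HI;
}

FragLib fraglib_from_list(const Rcpp::List &fl) {
  FragLib f;
  f.slot_pos = Rcpp::as<ivec>(fl["slot_pos"]);
  f.slot_len = Rcpp::as<ivec>(fl["slot_len"]);
  f.slot_off = Rcpp::as<ivec>(fl["slot_off"]);
  f.slot_n = Rcpp::as<ivec>(fl["slot_n"]);
  f.coords = Rcpp::as<mat>(fl["coords"]);
  return f;
}

static rowvec rand_unit(Xoshiro &rng) {
  rowvec v(3);
  for (int k = 0; k < 3; k++) v(k) = rng.normal();
  double n = norm(v);
  if (n < 1e-12) v = {1, 0, 0}; else v /= n;
  return v;
}

// rotate downstream atoms so that pseudo torsion tau_i (dihedral i-1..i+2)
// reaches `target`; pivot bond (i, i+1)
static void set_tau(mat &x, int i, double target) {
  double cur = pseudo_tau(x, i);
  rowvec axis = x.row(i + 1) - x.row(i);
  rotate_range(x, i + 2, x.n_rows - 1, x.row(i), axis, target - cur);
}

static void set_theta(mat &x, int i, double target) {
  rowvec u = x.row(i - 1) - x.row(i), v = x.row(i + 1) - x.row(i);
  rowvec n = cross(u, v);
  if (norm(n) < 1e-9) return;
  double cur = pseudo_theta(x, i);
  rotate_range(x, i + 1, x.n_rows - 1, x.row(i), n, cur - target);
}

MoveResult apply_move(int move_id, mat &x, const EModel &m,
                      const FragLib &fl, const imat &sse, Xoshiro &rng,
                      double mag) {
  MoveResult res;
  int L = x.n_rows;
  if (L < 5) return res;

  switch (move_id) {
  case 1: {  // torsion perturbation: rotate downstream about bond (i-1, i)
    int i = 1 + rng.randint(L - 2);
    rowvec axis = x.row(i) - x.row(i - 1);
    if (norm(axis) < 1e-9) return res;
    rotate_range(x, i + 1, L - 1, x.row(i), axis, rng.normal() * 0.45 * mag);
    res.ok = true; res.a = i + 1; res.b = L - 1;
    return res;
  }
  case 2: {  // single-residue displacement
    int i = rng.randint(L);
    rowvec old = x.row(i);
    for (int k = 0; k < 3; k++) x(i, k) += 0.3 * mag * rng.normal();
    bool ok = (i == 0 || bond_ok(x, i - 1, i)) && (i == L - 1 || bond_ok(x, i, i + 1));
    if (!ok) { x.row(i) = old; return res; }
    res.ok = true; res.a = i; res.b = i;
    return res;
  }
  case 3: {  // bond-angle perturbation at residue i
    int i = 1 + rng.randint(L - 2);
    rowvec u = x.row(i - 1) - x.row(i), v = x.row(i + 1) - x.row(i);
    rowvec n = cross(u, v);
    if (norm(n) < 1e-9) return res;
    rotate_range(x, i + 1, L - 1, x.row(i), n, rng.normal() * 0.17 * mag);
    res.ok = true; res.a = i + 1; res.b = L - 1;
    return res;
  }
  case 4: {  // reset residue i to the ideal angles of its SS state
    int i = 1 + rng.randint(L - 3);
    int st = m.ss(i);
    set_theta(x, i, m.theta0[st]);
    set_tau(x, i, m.tau0[st]);
    res.ok = true; res.a = i + 1; res.b = L - 1;
    return res;
  }
  case 5: {  // fragment substitution
    if (fl.empty()) return res;
    int s = rng.randint(fl.slot_pos.n_elem);
    int n = fl.slot_n(s);
    if (n == 0) return res;
    int len = fl.slot_len(s);
    int p = fl.slot_pos(s);
    if (len < 3 || p + len > L) return res;
    int f = rng.randint(n);
    mat frag = fl.coords.rows(fl.slot_off(s) + f * len,
                              fl.slot_off(s) + (f + 1) * len - 1);
    mat win = x.rows(p, p + len - 1);
    mat fit = kabsch_fit(frag, win);
    mat old = win;
    x.rows(p, p + len - 1) = fit;
    bool ok = (p == 0 || bond_ok(x, p - 1, p)) &&
              (p + len == L || bond_ok(x, p + len - 1, p + len));
    if (!ok) { x.rows(p, p + len - 1) = old; return res; }
    res.ok = true; res.a = p; res.b = p + len - 1;
    return res;
  }
  case 6: {  // crankshaft: rotate interior of (i, j) about the i->j axis
    int span = 3 + rng.randint(10);
    if (span >= L - 1) span = L - 2;
    int i = rng.randint(L - span);
    int j = i + span;
    rowvec axis = x.row(j) - x.row(i);
    if (norm(axis) < 1e-9) return res;
    rotate_range(x, i + 1, j - 1, x.row(i), axis, rng.normal() * 0.5 * mag);
    res.ok = true; res.a = i + 1; res.b = j - 1;
    return res;
  }
  case 7: {  // rigid shift of a short segment
    int len = 3 + rng.randint(8);
    if (len > L - 2) len = L - 2;
    int i = 1 + rng.randint(L - len - 1);
    int j = i + len - 1;
    rowvec dx(3);
    for (int k = 0; k < 3; k++) dx(k) = 0.4 * mag * rng.normal();
    mat old = x.rows(i, j);
    x.rows(i, j).each_row() += dx;
    if (!bond_ok(x, i - 1, i) || !bond_ok(x, j, j + 1)) {
      x.rows(i, j) = old; return res;
    }
    res.ok = true; res.a = i; res.b = j;
    return res;
  }
  case 8: {  // loop re-draw; downstream re-attached rigidly via local frames
    int len = 3 + rng.randint(6);
    if (len > L - 4) return res;
    int i = 2 + rng.randint(L - len - 3);  // i >= 2, i + len <= L - 2
    int j = i + len - 1;
    mat old = x;
    for (int r = i; r <= j; r++) {
      int st = m.ss(r);
      double th, ta;
      if (st != 0 && rng.u01() < 0.5) { th = m.theta0[st]; ta = m.tau0[st]; }
      else {
        th = (75.0 + 75.0 * rng.u01()) * M_PI / 180.0;
        ta = (2.0 * rng.u01() - 1.0) * M_PI;
      }
      x.row(r) = place_nerf(x.row(r - 3 >= 0 ? r - 3 : 0), x.row(r - 2),
                            x.row(r - 1), 3.8, th, ta);
    }
    if (j + 1 < L) {
      // map downstream through the frame change at residues (j-2, j-1, j)
      auto frame = [](const mat &y, int j) {
        rowvec e1 = y.row(j) - y.row(j - 1); e1 /= norm(e1);
        rowvec a = y.row(j - 2) - y.row(j - 1);
        rowvec e3 = cross(e1, a);
        if (norm(e3) < 1e-9) e3 = {0, 0, 1}; else e3 /= norm(e3);
        rowvec e2 = cross(e3, e1);
        mat F(3, 3);
        F.row(0) = e1; F.row(1) = e2; F.row(2) = e3;
        return F;
      };
      mat F0 = frame(old, j), F1 = frame(x, j);
      for (int r = j + 1; r < L; r++) {
        rowvec local = (old.row(r) - old.row(j)) * F0.t();
        x.row(r) = x.row(j) + local * F1;
      }
      res.b = L - 1;
    } else res.b = j;
    res.ok = true; res.a = i;
    return res;
  }
  case 9: {  // terminal-tail hinge rotation
    bool nterm = rng.u01() < 0.5;
    // hinges live in loops: pick a coil residue when one exists
    int i = 2 + rng.randint(L - 4);
    if (rng.u01() < 0.7) {
      std::vector<int> coil;
      for (int q = 2; q < L - 2; q++) if (m.ss(q) == 0) coil.push_back(q);
      if (!coil.empty()) i = coil[rng.randint(coil.size())];
    }
    rowvec axis = rand_unit(rng);
    double ang = rng.normal() * 0.8 * mag;
    if (nterm) {
      rotate_range(x, 0, i - 1, x.row(i), axis, ang);
      res.a = 0; res.b = i - 1;
    } else {
      rotate_range(x, i + 1, L - 1, x.row(i), axis, ang);
      res.a = i + 1; res.b = L - 1;
    }
    res.ok = true;
    return res;
  }
  case 10: case 11: {  // rigid SSE translation / rotation about its axis
    if (sse.n_rows == 0) return res;
    int k = rng.randint(sse.n_rows);
    int s = sse(k, 0), e = sse(k, 1);
    mat old = x.rows(s, e);
    if (move_id == 10) {
      rowvec dx(3);
      for (int q = 0; q < 3; q++) dx(q) = 0.4 * mag * rng.normal();
      x.rows(s, e).each_row() += dx;
    } else {
      rowvec axis = x.row(e) - x.row(s);
      if (norm(axis) < 1e-9) return res;
      rowvec c = mean(x.rows(s, e), 0);
      rotate_range(x, s, e, c, axis, rng.normal() * 0.5 * mag);
    }
    bool ok = (s == 0 || bond_ok(x, s - 1, s)) && (e == L - 1 || bond_ok(x, e, e + 1));
    if (!ok) { x.rows(s, e) = old; return res; }
    res.ok = true; res.a = s; res.b = e;
    return res;
  }
  }
  return res;
}

// Single-move R entry point, used by tests and diagnostics. Returns the
// proposal, the touched window (1-based) and whether the proposal succeeded.
// [[Rcpp::export(name = "cpp_propose_move")]]
Rcpp::List cpp_propose_move(const arma::mat &ca, int move_id,
                            const Rcpp::List &model, const Rcpp::List &fraglib,
                            const arma::imat &sse, int seed) {
  EModel m = model_from_list(model);
  FragLib fl = fraglib_from_list(fraglib);
  Xoshiro rng((uint64_t)seed);
  mat x = ca;
  imat sse0 = sse;
  if (sse0.n_rows > 0) sse0 -= 1;  // to 0-based
  MoveResult r = apply_move(move_id, x, m, fl, sse0, rng, 1.0);
  return Rcpp::List::create(
      Rcpp::Named("ok") = r.ok,
      Rcpp::Named("coords") = x,
      Rcpp::Named("window") = Rcpp::IntegerVector::create(r.a + 1, r.b + 1));
}
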