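// [[Rcpp::depends(RcppArmadillo)]]
#include "confold.h"
#include <chrono>
using namespace arma;

// Replica-exchange Monte Carlo fragment assembly. All replicas start from the
// supplied conformation; each cycle every replica attempts `moves_per_cycle`
// Metropolis moves at its own temperature, then adjacent replicas attempt
// configuration swaps (odd/even alternating pairing). Snapshots are taken
// from the low-temperature half of the ladder at a fixed cycle stride.
//
// config fields: temps (vec), n_cycles, moves_per_cycle, stride,
// level_probs_low (3), level_probs_high (3), monitor (k x 2, 1-based),
// max_seconds.
// [[Rcpp::export(name = "cpp_run_remc")]]
Rcpp::List cpp_run_remc(const arma::mat &init, const Rcpp::List &model,
                        const Rcpp::List &fraglib, const arma::imat &sse1,
                        const Rcpp::List &config, double seed) {
  EModel m = model_from_list(model);
  FragLib fl = fraglib_from_list(fraglib);
  vec temps = Rcpp::as<vec>(config["temps"]);
  int n_rep = temps.n_elem;
  int n_cycles = Rcpp::as<int>(config["n_cycles"]);
  int mpc = Rcpp::as<int>(config["moves_per_cycle"]);
  int stride = Rcpp::as<int>(config["stride"]);
  vec plo = Rcpp::as<vec>(config["level_probs_low"]);
  vec phi = Rcpp::as<vec>(config["level_probs_high"]);
  int snap_from = Rcpp::as<int>(config["snap_from"]);
  imat monitor = Rcpp::as<imat>(config["monitor"]);
  if (monitor.n_rows > 0) monitor -= 1;
  double max_seconds = Rcpp::as<double>(config["max_seconds"]);
  int L = init.n_rows;

  imat sse = sse1;
  if (sse.n_rows > 0) sse -= 1;

  // per-replica state and RNG streams (splitmix64 off the master seed)
  std::vector<mat> xs(n_rep, init), cbs(n_rep);
  std::vector<double> Es(n_rep);
  std::vector<Xoshiro> rngs;
  uint64_t ms = (uint64_t)seed;
  for (int k = 0; k < n_rep; k++) rngs.emplace_back(Xoshiro::splitmix64(ms));
  Xoshiro swap_rng(Xoshiro::splitmix64(ms));
  for (int k = 0; k < n_rep; k++) {
    cbs[k] = cbeta_coords(xs[k], m.is_gly);
    Es[k] = energy_total(xs[k], cbs[k], m);
  }

  // level probabilities per replica, annealed toward residue moves at low T
  mat lev(n_rep, 3);
  for (int k = 0; k < n_rep; k++) {
    double f = n_rep > 1 ? (double)k / (n_rep - 1) : 1.0;
    for (int q = 0; q < 3; q++) lev(k, q) = plo(q) + f * (phi(q) - plo(q));
    lev.row(k) /= accu(lev.row(k));
  }
  const int level_moves[3][4] = {{1, 2, 3, 4}, {5, 6, 7, 8}, {9, 10, 11, -1}};
  const int level_n[3] = {4, 4, 3};

  int n_low = std::max(1, n_rep / 2);
  std::vector<mat> snap_x;
  std::vector<double> snap_e;
  std::vector<int> snap_rep, snap_cyc;
  mat log_cyc(n_cycles, 3, fill::zeros);  // energy(rep0), satisfaction(rep0), acc rate
  auto t_start = std::chrono::steady_clock::now();
  int done = 0;
  bool timed_out = false;

  auto satisfaction = [&](const mat &cb) {
    if (monitor.n_rows == 0) return NA_REAL;
    int ok = 0;
    for (unsigned q = 0; q < monitor.n_rows; q++)
      if (norm(cb.row(monitor(q, 0)) - cb.row(monitor(q, 1))) < 8.0) ok++;
    return (double)ok / monitor.n_rows;
  };

  double t_max = temps(n_rep - 1);
  for (int cyc = 0; cyc < n_cycles; cyc++) {
    long n_acc = 0, n_try = 0;
    for (int k = 0; k < n_rep; k++) {
      Xoshiro &rng = rngs[k];
      double T = temps(k);
      // smaller perturbations at low temperature: refinement, not disruption
      double mag = std::max(0.35, std::sqrt(T / t_max));
      for (int mv = 0; mv < mpc; mv++) {
        double u = rng.u01();
        int level = u < lev(k, 0) ? 0 : (u < lev(k, 0) + lev(k, 1) ? 1 : 2);
        int mid = level_moves[level][rng.randint(level_n[level])];
        mat xo = xs[k];
        MoveResult r = apply_move(mid, xs[k], m, fl, sse, rng, mag);
        n_try++;
        if (!r.ok) { xs[k] = xo; continue; }
        mat cb1 = cbs[k];
        int clo = std::max(0, r.a - 1), chi = std::min(L - 1, r.b + 1);
        {  // refresh the C-beta cache on the touched stencil
          mat cbw = cbeta_coords(xs[k], m.is_gly);
          cb1.rows(clo, chi) = cbw.rows(clo, chi);
        }
        double dE = energy_delta_range(xo, cbs[k], xs[k], cb1, r.a, r.b, m);
        if (dE <= 0.0 || rng.u01() < std::exp(-dE / T)) {
          Es[k] += dE;
          cbs[k] = cb1;
          n_acc++;
        } else {
          xs[k] = xo;
        }
      }
      // guard against accumulated floating-point drift
      Es[k] = energy_total(xs[k], cbs[k], m);
    }
    // replica swaps, alternating odd/even pairing
    for (int k = cyc % 2; k + 1 < n_rep; k += 2) {
      double arg = (1.0 / temps(k) - 1.0 / temps(k + 1)) * (Es[k] - Es[k + 1]);
      if (arg >= 0.0 || swap_rng.u01() < std::exp(arg)) {
        std::swap(xs[k], xs[k + 1]);
        std::swap(cbs[k], cbs[k + 1]);
        std::swap(Es[k], Es[k + 1]);
      }
    }
    log_cyc(cyc, 0) = Es[0];
    log_cyc(cyc, 1) = satisfaction(cbs[0]);
    log_cyc(cyc, 2) = n_try > 0 ? (double)n_acc / n_try : 0.0;
    if (cyc + 1 > snap_from && (cyc + 1) % stride == 0) {
      for (int k = 0; k < n_low; k++) {
        snap_x.push_back(xs[k]);
        snap_e.push_back(Es[k]);
        snap_rep.push_back(k + 1);
        snap_cyc.push_back(cyc + 1);
      }
    }
    done = cyc + 1;
    double el = std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t_start).count();
    if (el > max_seconds) { timed_out = true; break; }
  }

  int ns = snap_x.size();
  mat stack(ns, 3 * L);
  for (int i = 0; i < ns; i++)
    stack.row(i) = vectorise(snap_x[i], 1);  // row-major: x1 y1 z1 x2 ...
  return Rcpp::List::create(
      Rcpp::Named("snapshots") = stack,
      Rcpp::Named("energy") = vec(snap_e),
      Rcpp::Named("replica") = Rcpp::IntegerVector(snap_rep.begin(), snap_rep.end()),
      Rcpp::Named("cycle") = Rcpp::IntegerVector(snap_cyc.begin(), snap_cyc.end()),
      Rcpp::Named("log") = (done > 0 ? mat(log_cyc.rows(0, done - 1))
                                     : mat(0, 3)),
      Rcpp::Named("cycles_done") = done,
      Rcpp::Named("timed_out") = timed_out,
      Rcpp::Named("final") = xs[0]);
}

// [[Rcpp::export(name = "cpp_u01")]]
Rcpp::NumericVector cpp_u01(int n, double seed) {
  Xoshiro rng((uint64_t)seed);
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rng.u01();
  return out;
}

// [[Rcpp::export(name = "cpp_metropolis")]]
Rcpp::LogicalVector cpp_metropolis(const arma::vec &dE, double T, int seed) {
  Xoshiro rng((uint64_t)seed);
  Rcpp::LogicalVector out(dE.n_elem);
  for (unsigned i = 0; i < dE.n_elem; i++)
    out[i] = dE(i) <= 0.0 || rng.u01() < std::exp(-dE(i) / T);
  return out;
}
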