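#ifndef CONFOLD_H
#define CONFOLD_H

#include <RcppArmadillo.h>
#include <cstdint>

// --- deterministic, platform-independent RNG (xoshiro256+ / splitmix64) ---
// The sampler must be bit-reproducible for a given seed and stable when the
// replica count changes, so each replica owns its own stream seeded through
// splitmix64 rather than sharing R's global RNG.
struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0,1)
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // integer in [0, n)
  int randint(int n) { return (int)(u01() * n) % n; }
  // standard normal (Box-Muller)
  double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = u01(), u2 = u01();
    while (u1 <= 1e-300) u1 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// --- geometry helpers (geom.cpp) ---
arma::mat cbeta_coords(const arma::mat &ca, const arma::ivec &is_gly);
double pseudo_theta(const arma::mat &ca, int i);            // angle at residue i (radians)
double pseudo_tau(const arma::mat &ca, int i);              // dihedral (i-1,i,i+1,i+2)
arma::rowvec place_nerf(const arma::rowvec &a, const arma::rowvec &b,
                        const arma::rowvec &c, double r, double theta, double tau);
void rotate_range(arma::mat &x, int from, int to, const arma::rowvec &origin,
                  const arma::rowvec &axis, double angle);
double kabsch_rmsd_core(const arma::mat &a, const arma::mat &b);
arma::mat kabsch_fit(const arma::mat &mobile, const arma::mat &ref);

// --- energy model (energy.cpp) ---
struct EModel {
  int L = 0;
  arma::imat rest;      // n x 2, 0-based (i, j)
  arma::vec restU;      // well depths U_ij (>0)
  arma::imat ppairs;    // m x 2, 0-based, distance-profile pairs
  arma::mat ptab;       // m x nbin energy lookup (0.5 A bins on [0, 40))
  int nbin = 80;
  double w_con = 1.0, w_dp = 3.0, w_ca = 1.0, w_ev = 1.0, w_ss = 0.5, w_rg = 0.2;
  double db = 6.0;      // gradient width (A); D = 8 + db
  arma::ivec is_gly;    // 1 if glycine (C-beta proxy = C-alpha)
  arma::ivec ss;        // 0 coil, 1 helix, 2 strand
  arma::vec ss_w;       // per-residue weight of the SS bias (0 unless confident H/E)
  double theta0[3] = {0, 0, 0}, tau0[3] = {0, 0, 0};  // ideal pseudo angles by state
  double rg0 = 0.0;     // target radius of gyration 2.2 * L^0.38
};

EModel model_from_list(const Rcpp::List &m);
double econ_core(double d, double U, double db);
arma::vec energy_terms(const arma::mat &ca, const arma::mat &cb, const EModel &m);
double energy_total(const arma::mat &ca, const arma::mat &cb, const EModel &m);
double energy_delta_range(const arma::mat &ca0, const arma::mat &cb0,
                          const arma::mat &ca1, const arma::mat &cb1,
                          int a, int b, const EModel &m);

// --- fragment library for the sampler (moves.cpp / remc.cpp) ---
struct FragLib {
  arma::ivec slot_pos;   // 0-based query start of each slot
  arma::ivec slot_len;
  arma::ivec slot_off;   // row offset of the slot's first fragment in coords
  arma::ivec slot_n;     // fragments in slot
  arma::mat coords;      // stacked fragment C-alpha coords (slot_n * len rows each)
  bool empty() const { return slot_pos.n_elem == 0; }
};
FragLib fraglib_from_list(const Rcpp::List &fl);

struct MoveResult {
  bool ok = false;
  int a = 0, b = 0;      // touched residue range (0-based, inclusive)
};
MoveResult apply_move(int move_id, arma::mat &x, const EModel &m,
                      const FragLib &fl, const arma::imat &sse, Xoshiro &rng,
                      double mag = 1.0);

#endif
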