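// [[Rcpp::depends(RcppArmadillo)]]
#include "confold.h"
#include <algorithm>
using namespace arma;

// Gapless threading: score every window of every library structure against
// every (position, length) slot of the query by mean substitution score plus
// a weighted secondary-structure match fraction; keep the top `topk` windows
// per slot. Sequences are 0-based integer-encoded over the scoring matrix's
// alphabet; ss codes are 0/1/2.
// [[Rcpp::export(name = "cpp_gapless_thread")]]
Rcpp::List cpp_gapless_thread(const arma::ivec &qseq, const arma::ivec &qss,
                              const Rcpp::List &lib_seq, const Rcpp::List &lib_ss,
                              const arma::mat &submat, const arma::ivec &lengths,
                              int topk, double w_ssm) {
  int L = qseq.n_elem, n_lib = lib_seq.size();
  std::vector<ivec> seqs(n_lib), sss(n_lib);
  for (int s = 0; s < n_lib; s++) {
    seqs[s] = Rcpp::as<ivec>(lib_seq[s]);
    sss[s] = Rcpp::as<ivec>(lib_ss[s]);
  }
  std::vector<int> o_pos, o_len, o_src, o_start, o_rank;
  std::vector<double> o_score;
  struct Hit { double score; int src, start; };
  for (unsigned li = 0; li < lengths.n_elem; li++) {
    int len = lengths(li);
    for (int p = 0; p + len <= L; p++) {
      std::vector<Hit> hits;
      for (int s = 0; s < n_lib; s++) {
        int Ls = seqs[s].n_elem;
        for (int w = 0; w + len <= Ls; w++) {
          double sub = 0.0; int ssm = 0;
          for (int k = 0; k < len; k++) {
            sub += submat(qseq(p + k), seqs[s](w + k));
            if (qss(p + k) == sss[s](w + k)) ssm++;
          }
          hits.push_back({sub / len + w_ssm * ssm / len, s, w});
        }
      }
      int keep = std::min((int)hits.size(), topk);
      std::partial_sort(hits.begin(), hits.begin() + keep, hits.end(),
                        [](const Hit &a, const Hit &b) {
                          if (a.score != b.score) return a.score > b.score;
                          if (a.src != b.src) return a.src < b.src;
                          return a.start < b.start;
                        });
      for (int r = 0; r < keep; r++) {
        o_pos.push_back(p + 1);
        o_len.push_back(len);
        o_src.push_back(hits[r].src + 1);
        o_start.push_back(hits[r].start + 1);
        o_rank.push_back(r + 1);
        o_score.push_back(hits[r].score);
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("pos") = Rcpp::IntegerVector(o_pos.begin(), o_pos.end()),
      Rcpp::Named("len") = Rcpp::IntegerVector(o_len.begin(), o_len.end()),
      Rcpp::Named("source") = Rcpp::IntegerVector(o_src.begin(), o_src.end()),
      Rcpp::Named("sstart") = Rcpp::IntegerVector(o_start.begin(), o_start.end()),
      Rcpp::Named("rank") = Rcpp::IntegerVector(o_rank.begin(), o_rank.end()),
      Rcpp::Named("score") = Rcpp::NumericVector(o_score.begin(), o_score.end()));
}
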