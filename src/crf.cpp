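// Linear-chain CRF primitives shared by the neural labeler and the classical
// feature-based baseline. All computations are in log space. Label indices are
// 1-based on the R side, 0-based internally.
#include <RcppArmadillo.h>
#include "crf_core.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using famhx::logsumexp_vec;

// Forward algorithm: log partition function over all label paths.
// emissions: n x L, trans: L x L (trans(i,j) = score of i -> j),
// start/stop: length-L boundary scores.
// [[Rcpp::export]]
double crf_log_partition_cpp(const arma::mat& emissions, const arma::mat& trans,
                             const arma::vec& start, const arma::vec& stop) {
  const arma::uword n = emissions.n_rows, L = emissions.n_cols;
  if (n == 0) return 0.0;
  arma::vec alpha = start + emissions.row(0).t();
  for (arma::uword t = 1; t < n; ++t) {
    arma::vec next(L);
    for (arma::uword j = 0; j < L; ++j)
      next(j) = logsumexp_vec(alpha + trans.col(j)) + emissions(t, j);
    alpha = next;
  }
  return logsumexp_vec(alpha + stop);
}

// Score of one labeled path.
// [[Rcpp::export]]
double crf_path_score_cpp(const arma::mat& emissions, const arma::mat& trans,
                          const arma::vec& start, const arma::vec& stop,
                          const arma::ivec& path) {
  const arma::uword n = emissions.n_rows;
  if (n == 0) return 0.0;
  double s = start(path(0) - 1) + emissions(0, path(0) - 1);
  for (arma::uword t = 1; t < n; ++t) {
    s += trans(path(t - 1) - 1, path(t) - 1) + emissions(t, path(t) - 1);
  }
  s += stop(path(n - 1) - 1);
  return s;
}

// Negative log likelihood of the gold path plus gradients w.r.t. emissions,
// transitions and boundary scores (expected counts minus observed counts),
// computed by forward-backward.
// [[Rcpp::export]]
List crf_nll_grad_cpp(const arma::mat& emissions, const arma::mat& trans,
                      const arma::vec& start, const arma::vec& stop,
                      const arma::ivec& gold) {
  arma::uvec g0(gold.n_elem);
  for (arma::uword t = 0; t < gold.n_elem; ++t) g0(t) = (arma::uword)(gold(t) - 1);
  famhx::CrfGrad res = famhx::crf_nll_grad_core(emissions, trans, start, stop, g0);
  return List::create(_["nll"] = res.nll, _["g_em"] = res.g_em,
                      _["g_trans"] = res.g_trans, _["g_start"] = res.g_start,
                      _["g_stop"] = res.g_stop);
}

// Viterbi decoding with optional hard transition constraints. allowed_trans
// and allowed_start are 0/1 masks; disallowed moves score -1e30. Ties resolve
// to the lowest label index (index_max returns the first maximum).
// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(const arma::mat& emissions, const arma::mat& trans,
                              const arma::vec& start, const arma::vec& stop,
                              Nullable<NumericMatrix> allowed_trans = R_NilValue,
                              Nullable<NumericVector> allowed_start = R_NilValue) {
  const arma::uword n = emissions.n_rows, L = emissions.n_cols;
  if (n == 0) return IntegerVector(0);
  const double NEG = -1e30;
  arma::mat tr = trans;
  arma::vec st = start;
  if (allowed_trans.isNotNull()) {
    arma::mat mask = as<arma::mat>(allowed_trans.get());
    tr.elem(arma::find(mask == 0)).fill(NEG);
  }
  if (allowed_start.isNotNull()) {
    arma::vec smask = as<arma::vec>(allowed_start.get());
    st.elem(arma::find(smask == 0)).fill(NEG);
  }
  arma::mat delta(n, L);
  arma::umat back(n, L, arma::fill::zeros);
  delta.row(0) = (st + emissions.row(0).t()).t();
  for (arma::uword t = 1; t < n; ++t) {
    for (arma::uword j = 0; j < L; ++j) {
      arma::vec cand = delta.row(t - 1).t() + tr.col(j);
      arma::uword bi = cand.index_max();
      delta(t, j) = cand(bi) + emissions(t, j);
      back(t, j) = bi;
    }
  }
  arma::vec fin = delta.row(n - 1).t() + stop;
  arma::uword cur = fin.index_max();
  IntegerVector out(n);
  out[n - 1] = (int)cur + 1;
  for (arma::uword t = n - 1; t > 0; --t) {
    cur = back(t, cur);
    out[t - 1] = (int)cur + 1;
  }
  return out;
}
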