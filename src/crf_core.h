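// Shared linear-chain CRF forward-backward core used by both the exported
// CRF primitives (crf.cpp) and the neural sequence labeler (nn.cpp).
#ifndef FAMHX_CRF_CORE_H
#define FAMHX_CRF_CORE_H

#include <RcppArmadillo.h>

namespace famhx {

inline double logsumexp_vec(const arma::vec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

struct CrfGrad {
  double nll;
  arma::mat g_em;
  arma::mat g_trans;
  arma::vec g_start;
  arma::vec g_stop;
};

// gold is 0-based here.
inline CrfGrad crf_nll_grad_core(const arma::mat& emissions, const arma::mat& trans,
                                 const arma::vec& start, const arma::vec& stop,
                                 const arma::uvec& gold) {
  const arma::uword n = emissions.n_rows, L = emissions.n_cols;
  CrfGrad out;
  out.g_em.zeros(n, L);
  out.g_trans.zeros(L, L);
  out.g_start.zeros(L);
  out.g_stop.zeros(L);
  out.nll = 0.0;
  if (n == 0) return out;

  arma::mat alpha(n, L), beta(n, L);
  alpha.row(0) = (start + emissions.row(0).t()).t();
  for (arma::uword t = 1; t < n; ++t)
    for (arma::uword j = 0; j < L; ++j)
      alpha(t, j) = logsumexp_vec(alpha.row(t - 1).t() + trans.col(j)) + emissions(t, j);
  beta.row(n - 1) = stop.t();
  for (arma::uword t = n - 1; t > 0; --t)
    for (arma::uword i = 0; i < L; ++i)
      beta(t - 1, i) = logsumexp_vec(trans.row(i).t() + emissions.row(t).t() + beta.row(t).t());
  const double logZ = logsumexp_vec(alpha.row(n - 1).t() + stop);

  for (arma::uword t = 0; t < n; ++t)
    out.g_em.row(t) = arma::exp(alpha.row(t) + beta.row(t) - logZ);
  for (arma::uword t = 1; t < n; ++t)
    for (arma::uword i = 0; i < L; ++i)
      for (arma::uword j = 0; j < L; ++j)
        out.g_trans(i, j) += std::exp(alpha(t - 1, i) + trans(i, j) + emissions(t, j) +
                                      beta(t, j) - logZ);
  out.g_start = arma::exp(start + emissions.row(0).t() + beta.row(0).t() - logZ);
  out.g_stop = arma::exp(alpha.row(n - 1).t() + stop - logZ);

  double gold_score = start(gold(0)) + emissions(0, gold(0));
  out.g_em(0, gold(0)) -= 1.0;
  for (arma::uword t = 1; t < n; ++t) {
    gold_score += trans(gold(t - 1), gold(t)) + emissions(t, gold(t));
    out.g_em(t, gold(t)) -= 1.0;
    out.g_trans(gold(t - 1), gold(t)) -= 1.0;
  }
  gold_score += stop(gold(n - 1));
  out.g_start(gold(0)) -= 1.0;
  out.g_stop(gold(n - 1)) -= 1.0;
  out.nll = logZ - gold_score;
  return out;
}

}  // namespace famhx

#endif
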