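// Compiled core of the neural sequence labeler: character-level CNN with
// max-pooling, bidirectional LSTM over concatenated word / character / PoS /
// family-flag / concept embeddings, and a linear-chain CRF (or per-token
// softmax) objective. Forward and backward passes are written out by hand;
// gradients are returned to R, where the SGD loop lives.
//
// Parameter list layout (all matrices; names fixed):
//   Ew (Vw x dw)  word embeddings        Ec (Vc x dc)  character embeddings
//   Ep (Vp x dp)  PoS embeddings         Eu (Vu x du)  concept (CUI) embeddings
//   Wconv (nf x k*dc), bconv (nf)        character CNN
//   Wf/Uf/bf, Wb/Ub/bb (4H x D, 4H x H, 4H)  forward / backward LSTM
//   Wo (L x 2H), bo (L)                  emission projection
//   trans (L x L), start (L), stop (L)   CRF scores
//
// Sentence encoding (1-based indices from R):
//   word: ivec, chars: list of ivec, pos: ivec, cui: ivec, flag: numeric vec,
//   gold: ivec (absent/empty for prediction).
#include <RcppArmadillo.h>
#include <random>
#include "crf_core.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dims {
  arma::uword dw, dc, dp, du, nf, k, H, L, D;
};

Dims read_dims(const List& params) {
  Dims d;
  d.dw = as<arma::mat>(params["Ew"]).n_cols;
  d.dc = as<arma::mat>(params["Ec"]).n_cols;
  d.dp = as<arma::mat>(params["Ep"]).n_cols;
  d.du = as<arma::mat>(params["Eu"]).n_cols;
  arma::mat Wconv = as<arma::mat>(params["Wconv"]);
  d.nf = Wconv.n_rows;
  d.k = Wconv.n_cols / d.dc;
  d.H = as<arma::mat>(params["Uf"]).n_cols;
  d.L = as<arma::mat>(params["Wo"]).n_rows;
  d.D = as<arma::mat>(params["Wf"]).n_cols;
  return d;
}

struct CharCache {
  arma::mat Xd;       // dropped-out char embeddings, m x dc
  arma::mat mask;     // dropout mask (already scaled), m x dc
  arma::uvec amax;    // argmax position per filter
  arma::vec r;        // pooled tanh outputs, nf
};

// Character CNN forward for one word. chars are 0-based row indices into Ec.
void char_forward(const arma::mat& Ec, const arma::mat& Wconv, const arma::vec& bconv,
                  const arma::uvec& chars, arma::uword k, double dropout, bool train,
                  std::mt19937& gen, CharCache& cc) {
  const arma::uword m = chars.n_elem, dc = Ec.n_cols, nf = Wconv.n_rows;
  cc.r.zeros(nf);
  cc.amax.zeros(nf);
  if (m == 0) { cc.Xd.set_size(0, dc); cc.mask.set_size(0, dc); return; }
  arma::mat X(m, dc);
  for (arma::uword i = 0; i < m; ++i) X.row(i) = Ec.row(chars(i));
  cc.mask.ones(m, dc);
  if (train && dropout > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    const double scale = 1.0 / (1.0 - dropout);
    for (arma::uword i = 0; i < m; ++i)
      for (arma::uword j = 0; j < dc; ++j)
        cc.mask(i, j) = (unif(gen) < dropout) ? 0.0 : scale;
  }
  cc.Xd = X % cc.mask;
  const arma::uword pad = (k - 1) / 2;
  arma::mat Z(m, nf, arma::fill::zeros);
  arma::vec win(k * dc);
  for (arma::uword i = 0; i < m; ++i) {
    win.zeros();
    for (arma::uword o = 0; o < k; ++o) {
      long long row = (long long)i + (long long)o - (long long)pad;
      if (row >= 0 && row < (long long)m)
        win.subvec(o * dc, (o + 1) * dc - 1) = cc.Xd.row((arma::uword)row).t();
    }
    Z.row(i) = arma::tanh(Wconv * win + bconv).t();
  }
  for (arma::uword f = 0; f < nf; ++f) {
    arma::uword bi = Z.col(f).index_max();
    cc.amax(f) = bi;
    cc.r(f) = Z(bi, f);
  }
}

// Backward through the char CNN for one word; accumulates into gradients.
void char_backward(const arma::mat& Wconv, const arma::uvec& chars, arma::uword k,
                   const CharCache& cc, const arma::vec& dr, arma::mat& gEc,
                   arma::mat& gWconv, arma::vec& gbconv) {
  const arma::uword m = cc.Xd.n_rows;
  if (m == 0) return;
  const arma::uword dc = cc.Xd.n_cols, nf = Wconv.n_rows;
  const arma::uword pad = (k - 1) / 2;
  arma::mat dX(m, dc, arma::fill::zeros);
  arma::vec win(k * dc);
  for (arma::uword f = 0; f < nf; ++f) {
    const double dpre = dr(f) * (1.0 - cc.r(f) * cc.r(f));
    if (dpre == 0.0) continue;
    const arma::uword i = cc.amax(f);
    win.zeros();
    for (arma::uword o = 0; o < k; ++o) {
      long long row = (long long)i + (long long)o - (long long)pad;
      if (row >= 0 && row < (long long)m) {
        win.subvec(o * dc, (o + 1) * dc - 1) = cc.Xd.row((arma::uword)row).t();
        dX.row((arma::uword)row) += dpre * Wconv(f, arma::span(o * dc, (o + 1) * dc - 1));
      }
    }
    gWconv.row(f) += dpre * win.t();
    gbconv(f) += dpre;
  }
  dX %= cc.mask;  // through dropout
  for (arma::uword i = 0; i < m; ++i) gEc.row(chars(i)) += dX.row(i);
}

struct LstmCache {
  // per time step (in processing order)
  std::vector<arma::vec> i, f, o, g, c, h, x;
};

void lstm_forward(const arma::mat& W, const arma::mat& U, const arma::vec& b,
                  const std::vector<arma::vec>& xs, arma::uword H, LstmCache& lc) {
  const arma::uword n = xs.size();
  lc.i.resize(n); lc.f.resize(n); lc.o.resize(n); lc.g.resize(n);
  lc.c.resize(n); lc.h.resize(n); lc.x = xs;
  arma::vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    arma::vec z = W * xs[t] + U * hprev + b;
    arma::vec zi = z.subvec(0, H - 1), zf = z.subvec(H, 2 * H - 1),
              zo = z.subvec(2 * H, 3 * H - 1), zg = z.subvec(3 * H, 4 * H - 1);
    lc.i[t] = 1.0 / (1.0 + arma::exp(-zi));
    lc.f[t] = 1.0 / (1.0 + arma::exp(-zf));
    lc.o[t] = 1.0 / (1.0 + arma::exp(-zo));
    lc.g[t] = arma::tanh(zg);
    lc.c[t] = lc.f[t] % cprev + lc.i[t] % lc.g[t];
    lc.h[t] = lc.o[t] % arma::tanh(lc.c[t]);
    hprev = lc.h[t];
    cprev = lc.c[t];
  }
}

// dh_list: gradient w.r.t. h_t (processing order). Returns dx per step and
// accumulates into gW/gU/gb.
void lstm_backward(const arma::mat& W, const arma::mat& U, const LstmCache& lc,
                   const std::vector<arma::vec>& dh_list, arma::uword H,
                   arma::mat& gW, arma::mat& gU, arma::vec& gb,
                   std::vector<arma::vec>& dx_out) {
  const arma::uword n = lc.h.size();
  dx_out.assign(n, arma::vec());
  arma::vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (arma::uword tt = n; tt > 0; --tt) {
    const arma::uword t = tt - 1;
    arma::vec dh = dh_list[t] + dh_next;
    arma::vec tc = arma::tanh(lc.c[t]);
    arma::vec dc = dc_next + dh % lc.o[t] % (1.0 - tc % tc);
    arma::vec do_ = dh % tc;
    arma::vec cprev = (t == 0) ? arma::vec(H, arma::fill::zeros) : lc.c[t - 1];
    arma::vec hprev = (t == 0) ? arma::vec(H, arma::fill::zeros) : lc.h[t - 1];
    arma::vec di = dc % lc.g[t];
    arma::vec df = dc % cprev;
    arma::vec dg = dc % lc.i[t];
    dc_next = dc % lc.f[t];
    arma::vec dz(4 * H);
    dz.subvec(0, H - 1) = di % lc.i[t] % (1.0 - lc.i[t]);
    dz.subvec(H, 2 * H - 1) = df % lc.f[t] % (1.0 - lc.f[t]);
    dz.subvec(2 * H, 3 * H - 1) = do_ % lc.o[t] % (1.0 - lc.o[t]);
    dz.subvec(3 * H, 4 * H - 1) = dg % (1.0 - lc.g[t] % lc.g[t]);
    gW += dz * lc.x[t].t();
    gU += dz * hprev.t();
    gb += dz;
    dx_out[t] = W.t() * dz;
    dh_next = U.t() * dz;
  }
}

struct SentCache {
  arma::uvec word, pos, cui, gold;
  std::vector<arma::uvec> chars;
  arma::vec flag;
  std::vector<CharCache> cc;
  std::vector<arma::vec> x;       // after input dropout
  std::vector<arma::vec> xmask;   // input dropout masks (scaled)
  LstmCache fwd, bwd;
  arma::mat emissions;            // n x L
};

arma::uvec as_index0(SEXP v) {
  arma::ivec iv = as<arma::ivec>(v);
  arma::uvec out(iv.n_elem);
  for (arma::uword t = 0; t < iv.n_elem; ++t) out(t) = (arma::uword)(iv(t) - 1);
  return out;
}

void sent_forward(const List& params, const Dims& d, const List& sent,
                  double dropout, bool train, std::mt19937& gen, SentCache& sc) {
  const arma::mat Ew = as<arma::mat>(params["Ew"]), Ec = as<arma::mat>(params["Ec"]),
                  Ep = as<arma::mat>(params["Ep"]), Eu = as<arma::mat>(params["Eu"]),
                  Wconv = as<arma::mat>(params["Wconv"]);
  const arma::vec bconv = as<arma::vec>(params["bconv"]);
  const arma::mat Wf = as<arma::mat>(params["Wf"]), Uf = as<arma::mat>(params["Uf"]),
                  Wb = as<arma::mat>(params["Wb"]), Ub = as<arma::mat>(params["Ub"]),
                  Wo = as<arma::mat>(params["Wo"]);
  const arma::vec bf = as<arma::vec>(params["bf"]), bb = as<arma::vec>(params["bb"]),
                  bo = as<arma::vec>(params["bo"]);

  sc.word = as_index0(sent["word"]);
  sc.pos = as_index0(sent["pos"]);
  sc.cui = as_index0(sent["cui"]);
  sc.flag = as<arma::vec>(sent["flag"]);
  List chl = sent["chars"];
  const arma::uword n = sc.word.n_elem;
  sc.chars.resize(n);
  sc.cc.resize(n);
  sc.x.resize(n);
  sc.xmask.resize(n);

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double scale = 1.0 / (1.0 - dropout);
  for (arma::uword t = 0; t < n; ++t) {
    sc.chars[t] = as_index0(chl[t]);
    char_forward(Ec, Wconv, bconv, sc.chars[t], d.k, dropout, train, gen, sc.cc[t]);
    arma::vec x(d.D);
    x.subvec(0, d.dw - 1) = Ew.row(sc.word(t)).t();
    x.subvec(d.dw, d.dw + d.nf - 1) = sc.cc[t].r;
    x.subvec(d.dw + d.nf, d.dw + d.nf + d.dp - 1) = Ep.row(sc.pos(t)).t();
    x(d.dw + d.nf + d.dp) = sc.flag(t);
    x.subvec(d.dw + d.nf + d.dp + 1, d.D - 1) = Eu.row(sc.cui(t)).t();
    arma::vec m(d.D, arma::fill::ones);
    if (train && dropout > 0)
      for (arma::uword j = 0; j < d.D; ++j) m(j) = (unif(gen) < dropout) ? 0.0 : scale;
    sc.xmask[t] = m;
    sc.x[t] = x % m;
  }
  lstm_forward(Wf, Uf, bf, sc.x, d.H, sc.fwd);
  std::vector<arma::vec> xr(n);
  for (arma::uword t = 0; t < n; ++t) xr[t] = sc.x[n - 1 - t];
  lstm_forward(Wb, Ub, bb, xr, d.H, sc.bwd);
  sc.emissions.set_size(n, d.L);
  for (arma::uword t = 0; t < n; ++t) {
    arma::vec h(2 * d.H);
    h.subvec(0, d.H - 1) = sc.fwd.h[t];
    h.subvec(d.H, 2 * d.H - 1) = sc.bwd.h[n - 1 - t];
    sc.emissions.row(t) = (Wo * h + bo).t();
  }
}

}  // namespace

// Character CNN representation of one word (exported for testing the layer
// contract directly).
// [[Rcpp::export]]
arma::vec nn_char_repr_cpp(const List& params, const IntegerVector& chars,
                           double dropout, bool train, int seed) {
  Dims d = read_dims(params);
  std::mt19937 gen((unsigned)seed);
  CharCache cc;
  arma::uvec ch(chars.size());
  for (int i = 0; i < chars.size(); ++i) ch(i) = (arma::uword)(chars[i] - 1);
  char_forward(as<arma::mat>(params["Ec"]), as<arma::mat>(params["Wconv"]),
               as<arma::vec>(params["bconv"]), ch, d.k, dropout, train, gen, cc);
  return cc.r;
}

// Emission matrices for a batch of sentences (evaluation mode: no dropout).
// [[Rcpp::export]]
List nn_emissions_cpp(const List& params, const List& sentences) {
  Dims d = read_dims(params);
  std::mt19937 gen(0);
  List out(sentences.size());
  for (int s = 0; s < sentences.size(); ++s) {
    SentCache sc;
    sent_forward(params, d, sentences[s], 0.0, false, gen, sc);
    out[s] = sc.emissions;
  }
  return out;
}

// Loss and gradients summed over a batch. mode: 0 = CRF negative log
// likelihood, 1 = per-token softmax cross-entropy. Returns gradients with the
// same shapes/names as the parameters.
// [[Rcpp::export]]
List nn_batch_grad_cpp(const List& params, const List& sentences, double dropout,
                       int mode, int seed) {
  Dims d = read_dims(params);
  const arma::mat Wf = as<arma::mat>(params["Wf"]), Uf = as<arma::mat>(params["Uf"]),
                  Wb = as<arma::mat>(params["Wb"]), Ub = as<arma::mat>(params["Ub"]),
                  Wo = as<arma::mat>(params["Wo"]), Wconv = as<arma::mat>(params["Wconv"]),
                  trans = as<arma::mat>(params["trans"]);
  const arma::vec start = as<arma::vec>(params["start"]), stop = as<arma::vec>(params["stop"]);

  arma::mat gEw(as<arma::mat>(params["Ew"]).n_rows, d.dw, arma::fill::zeros);
  arma::mat gEc(as<arma::mat>(params["Ec"]).n_rows, d.dc, arma::fill::zeros);
  arma::mat gEp(as<arma::mat>(params["Ep"]).n_rows, d.dp, arma::fill::zeros);
  arma::mat gEu(as<arma::mat>(params["Eu"]).n_rows, d.du, arma::fill::zeros);
  arma::mat gWconv(d.nf, d.k * d.dc, arma::fill::zeros);
  arma::vec gbconv(d.nf, arma::fill::zeros);
  arma::mat gWf(4 * d.H, d.D, arma::fill::zeros), gUf(4 * d.H, d.H, arma::fill::zeros);
  arma::mat gWb(4 * d.H, d.D, arma::fill::zeros), gUb(4 * d.H, d.H, arma::fill::zeros);
  arma::vec gbf(4 * d.H, arma::fill::zeros), gbb(4 * d.H, arma::fill::zeros);
  arma::mat gWo(d.L, 2 * d.H, arma::fill::zeros);
  arma::vec gbo(d.L, arma::fill::zeros);
  arma::mat gtrans(d.L, d.L, arma::fill::zeros);
  arma::vec gstart(d.L, arma::fill::zeros), gstop(d.L, arma::fill::zeros);

  double loss = 0.0;
  long long n_tokens = 0;
  std::mt19937 gen((unsigned)seed);

  for (int s = 0; s < sentences.size(); ++s) {
    List sent = sentences[s];
    SentCache sc;
    sent_forward(params, d, sent, dropout, true, gen, sc);
    const arma::uword n = sc.word.n_elem;
    if (n == 0) continue;
    n_tokens += (long long)n;
    arma::uvec gold = as_index0(sent["gold"]);

    arma::mat g_em(n, d.L, arma::fill::zeros);
    if (mode == 0) {
      famhx::CrfGrad cg = famhx::crf_nll_grad_core(sc.emissions, trans, start, stop, gold);
      loss += cg.nll;
      g_em = cg.g_em;
      gtrans += cg.g_trans;
      gstart += cg.g_start;
      gstop += cg.g_stop;
    } else {
      for (arma::uword t = 0; t < n; ++t) {
        arma::vec e = sc.emissions.row(t).t();
        double lz = famhx::logsumexp_vec(e);
        arma::vec p = arma::exp(e - lz);
        loss += lz - e(gold(t));
        p(gold(t)) -= 1.0;
        g_em.row(t) = p.t();
      }
    }

    // emissions -> h, Wo, bo
    std::vector<arma::vec> dh_f(n), dh_b(n);
    for (arma::uword t = 0; t < n; ++t) {
      arma::vec gt = g_em.row(t).t();
      arma::vec h(2 * d.H);
      h.subvec(0, d.H - 1) = sc.fwd.h[t];
      h.subvec(d.H, 2 * d.H - 1) = sc.bwd.h[n - 1 - t];
      gWo += gt * h.t();
      gbo += gt;
      arma::vec dh = Wo.t() * gt;
      dh_f[t] = dh.subvec(0, d.H - 1);
      // backward LSTM processes reversed order; its step for token t is n-1-t
      arma::vec db = dh.subvec(d.H, 2 * d.H - 1);
      dh_b[n - 1 - t] = db;
    }
    std::vector<arma::vec> dx_f, dx_b;
    lstm_backward(Wf, Uf, sc.fwd, dh_f, d.H, gWf, gUf, gbf, dx_f);
    lstm_backward(Wb, Ub, sc.bwd, dh_b, d.H, gWb, gUb, gbb, dx_b);

    for (arma::uword t = 0; t < n; ++t) {
      arma::vec dx = dx_f[t] + dx_b[n - 1 - t];
      dx %= sc.xmask[t];  // through input dropout
      gEw.row(sc.word(t)) += dx.subvec(0, d.dw - 1).t();
      arma::vec dr = dx.subvec(d.dw, d.dw + d.nf - 1);
      char_backward(Wconv, sc.chars[t], d.k, sc.cc[t], dr, gEc, gWconv, gbconv);
      gEp.row(sc.pos(t)) += dx.subvec(d.dw + d.nf, d.dw + d.nf + d.dp - 1).t();
      gEu.row(sc.cui(t)) += dx.subvec(d.dw + d.nf + d.dp + 1, d.D - 1).t();
      // family flag is an observed input; no gradient needed
    }
  }

  List grads = List::create(
      _["Ew"] = gEw, _["Ec"] = gEc, _["Ep"] = gEp, _["Eu"] = gEu,
      _["Wconv"] = gWconv, _["bconv"] = gbconv,
      _["Wf"] = gWf, _["Uf"] = gUf, _["bf"] = gbf,
      _["Wb"] = gWb, _["Ub"] = gUb, _["bb"] = gbb,
      _["Wo"] = gWo, _["bo"] = gbo,
      _["trans"] = gtrans, _["start"] = gstart, _["stop"] = gstop);
  return List::create(_["loss"] = loss, _["n_tokens"] = n_tokens, _["grads"] = grads);
}
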