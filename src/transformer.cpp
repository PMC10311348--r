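// Transformer encoder-decoder for residue labeling: forward pass, exact
// reverse-mode gradients, and KV-cached greedy decoding.
//
// Conventions: activations are arma::mat with rows = sequence positions.
// Residue tokens are 1..21 (21 = shared PAD/UNK), label tokens 1..9
// (9 = BOS), organism groups 1..4. Additive attention masks use NEG_MASK
// rather than -inf so that a fully masked row can never produce NaN.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

static const double NEG_MASK = -1e30;
static const double LN_EPS = 1e-5;

struct Cfg {
  int d, dS, H, Lenc, Ldec, ed, N;
  double dropout, dropout_enc;
  int dm() const { return d + dS; }
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.d = as<int>(cfg["d"]);
  c.dS = as<int>(cfg["dS"]);
  c.H = as<int>(cfg["H"]);
  c.Lenc = as<int>(cfg["L_enc"]);
  c.Ldec = as<int>(cfg["L_dec"]);
  c.ed = as<int>(cfg["ed"]);
  c.N = as<int>(cfg["N"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.dropout_enc = as<double>(cfg["dropout_enc"]);
  return c;
}

struct EncLayer { mat WQ, WK, WV, WO, W1, W2; vec b1, b2, ln1g, ln1b, ln2g, ln2b; };
struct DecLayer {
  mat sWQ, sWK, sWV, sWO, cWQ, cWK, cWV, cWO, W1, W2;
  vec b1, b2, ln1g, ln1b, ln2g, ln2b, ln3g, ln3b;
};
struct Params {
  mat Wa, WP, Wy, WG, WOout;
  std::vector<EncLayer> enc;
  std::vector<DecLayer> dec;
};

// zero-copy views onto the R-owned parameter matrices (read-only use)
static mat pmat(const List& p, const std::string& nm) {
  SEXP s = p[nm];
  if (TYPEOF(s) != REALSXP) stop("parameter %s must be numeric", nm.c_str());
  SEXP dim = Rf_getAttrib(s, R_DimSymbol);
  if (dim == R_NilValue || Rf_length(dim) != 2) stop("parameter %s must be a matrix", nm.c_str());
  return mat(REAL(s), INTEGER(dim)[0], INTEGER(dim)[1], false, true);
}

static vec pvec(const List& p, const std::string& nm) {
  SEXP s = p[nm];
  if (TYPEOF(s) != REALSXP) stop("parameter %s must be numeric", nm.c_str());
  return vec(REAL(s), Rf_xlength(s), false, true);
}

static Params parse_params(const List& p, const Cfg& c) {
  Params P;
  P.Wa = pmat(p, "Wa");
  P.WP = pmat(p, "WP");
  P.Wy = pmat(p, "Wy");
  P.WG = pmat(p, "WG");
  P.WOout = pmat(p, "WO_out");
  for (int l = 1; l <= c.Lenc; ++l) {
    std::string pre = "e" + std::to_string(l) + "_";
    EncLayer L;
    L.WQ = pmat(p, pre + "WQ"); L.WK = pmat(p, pre + "WK");
    L.WV = pmat(p, pre + "WV"); L.WO = pmat(p, pre + "WO");
    L.W1 = pmat(p, pre + "W1"); L.W2 = pmat(p, pre + "W2");
    L.b1 = pvec(p, pre + "b1"); L.b2 = pvec(p, pre + "b2");
    L.ln1g = pvec(p, pre + "ln1_g"); L.ln1b = pvec(p, pre + "ln1_b");
    L.ln2g = pvec(p, pre + "ln2_g"); L.ln2b = pvec(p, pre + "ln2_b");
    P.enc.push_back(std::move(L));
  }
  for (int l = 1; l <= c.Ldec; ++l) {
    std::string pre = "d" + std::to_string(l) + "_";
    DecLayer L;
    L.sWQ = pmat(p, pre + "sWQ"); L.sWK = pmat(p, pre + "sWK");
    L.sWV = pmat(p, pre + "sWV"); L.sWO = pmat(p, pre + "sWO");
    L.cWQ = pmat(p, pre + "cWQ"); L.cWK = pmat(p, pre + "cWK");
    L.cWV = pmat(p, pre + "cWV"); L.cWO = pmat(p, pre + "cWO");
    L.W1 = pmat(p, pre + "W1"); L.W2 = pmat(p, pre + "W2");
    L.b1 = pvec(p, pre + "b1"); L.b2 = pvec(p, pre + "b2");
    L.ln1g = pvec(p, pre + "ln1_g"); L.ln1b = pvec(p, pre + "ln1_b");
    L.ln2g = pvec(p, pre + "ln2_g"); L.ln2b = pvec(p, pre + "ln2_b");
    L.ln3g = pvec(p, pre + "ln3_g"); L.ln3b = pvec(p, pre + "ln3_b");
    P.dec.push_back(std::move(L));
  }
  return P;
}

// Gradient accumulator mirroring Params, zero-initialized.
struct Grads {
  Params g;
  Grads(const Params& P) {
    g.Wa = arma::zeros(arma::size(P.Wa));
    g.WP = arma::zeros(arma::size(P.WP));
    g.Wy = arma::zeros(arma::size(P.Wy));
    g.WG = arma::zeros(arma::size(P.WG));
    g.WOout = arma::zeros(arma::size(P.WOout));
    for (const auto& L : P.enc) {
      EncLayer Z;
      Z.WQ = arma::zeros(arma::size(L.WQ)); Z.WK = arma::zeros(arma::size(L.WK));
      Z.WV = arma::zeros(arma::size(L.WV)); Z.WO = arma::zeros(arma::size(L.WO));
      Z.W1 = arma::zeros(arma::size(L.W1)); Z.W2 = arma::zeros(arma::size(L.W2));
      Z.b1 = arma::zeros(arma::size(L.b1)); Z.b2 = arma::zeros(arma::size(L.b2));
      Z.ln1g = arma::zeros(arma::size(L.ln1g)); Z.ln1b = arma::zeros(arma::size(L.ln1b));
      Z.ln2g = arma::zeros(arma::size(L.ln2g)); Z.ln2b = arma::zeros(arma::size(L.ln2b));
      g.enc.push_back(std::move(Z));
    }
    for (const auto& L : P.dec) {
      DecLayer Z;
      Z.sWQ = arma::zeros(arma::size(L.sWQ)); Z.sWK = arma::zeros(arma::size(L.sWK));
      Z.sWV = arma::zeros(arma::size(L.sWV)); Z.sWO = arma::zeros(arma::size(L.sWO));
      Z.cWQ = arma::zeros(arma::size(L.cWQ)); Z.cWK = arma::zeros(arma::size(L.cWK));
      Z.cWV = arma::zeros(arma::size(L.cWV)); Z.cWO = arma::zeros(arma::size(L.cWO));
      Z.W1 = arma::zeros(arma::size(L.W1)); Z.W2 = arma::zeros(arma::size(L.W2));
      Z.b1 = arma::zeros(arma::size(L.b1)); Z.b2 = arma::zeros(arma::size(L.b2));
      Z.ln1g = arma::zeros(arma::size(L.ln1g)); Z.ln1b = arma::zeros(arma::size(L.ln1b));
      Z.ln2g = arma::zeros(arma::size(L.ln2g)); Z.ln2b = arma::zeros(arma::size(L.ln2b));
      Z.ln3g = arma::zeros(arma::size(L.ln3g)); Z.ln3b = arma::zeros(arma::size(L.ln3b));
      g.dec.push_back(std::move(Z));
    }
  }
};

static List grads_to_list(const Grads& G, const Cfg& c) {
  List out;
  out["Wa"] = G.g.Wa; out["WP"] = G.g.WP; out["Wy"] = G.g.Wy;
  out["WG"] = G.g.WG; out["WO_out"] = G.g.WOout;
  for (int l = 1; l <= c.Lenc; ++l) {
    std::string pre = "e" + std::to_string(l) + "_";
    const EncLayer& L = G.g.enc[l - 1];
    out[pre + "WQ"] = L.WQ; out[pre + "WK"] = L.WK; out[pre + "WV"] = L.WV;
    out[pre + "WO"] = L.WO; out[pre + "W1"] = L.W1; out[pre + "W2"] = L.W2;
    out[pre + "b1"] = L.b1; out[pre + "b2"] = L.b2;
    out[pre + "ln1_g"] = L.ln1g; out[pre + "ln1_b"] = L.ln1b;
    out[pre + "ln2_g"] = L.ln2g; out[pre + "ln2_b"] = L.ln2b;
  }
  for (int l = 1; l <= c.Ldec; ++l) {
    std::string pre = "d" + std::to_string(l) + "_";
    const DecLayer& L = G.g.dec[l - 1];
    out[pre + "sWQ"] = L.sWQ; out[pre + "sWK"] = L.sWK;
    out[pre + "sWV"] = L.sWV; out[pre + "sWO"] = L.sWO;
    out[pre + "cWQ"] = L.cWQ; out[pre + "cWK"] = L.cWK;
    out[pre + "cWV"] = L.cWV; out[pre + "cWO"] = L.cWO;
    out[pre + "W1"] = L.W1; out[pre + "W2"] = L.W2;
    out[pre + "b1"] = L.b1; out[pre + "b2"] = L.b2;
    out[pre + "ln1_g"] = L.ln1g; out[pre + "ln1_b"] = L.ln1b;
    out[pre + "ln2_g"] = L.ln2g; out[pre + "ln2_b"] = L.ln2b;
    out[pre + "ln3_g"] = L.ln3g; out[pre + "ln3_b"] = L.ln3b;
  }
  return out;
}

// ---------------------------------------------------------------- primitives

static mat softmax_rows(mat S) {
  vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  vec s = arma::sum(S, 1);
  S.each_col() /= s;
  return S;
}

// Sinusoidal positional table, dS x (N+1); position index i runs 1..N+1.
static mat make_ws(int dS, int N) {
  mat WS(dS, N + 1);
  for (int k = 0; k < dS / 2; ++k) {
    double denom = std::pow(10000.0, (2.0 * k) / dS);
    for (int i = 1; i <= N + 1; ++i) {
      WS(2 * k, i - 1) = std::sin(i / denom);
      WS(2 * k + 1, i - 1) = std::cos(i / denom);
    }
  }
  return WS;
}

struct LNCache { mat xhat; vec invstd; };

static mat layernorm_fwd(const mat& x, const vec& g, const vec& b, LNCache& cache) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec var = arma::mean(arma::square(xc), 1);
  cache.invstd = 1.0 / arma::sqrt(var + LN_EPS);
  cache.xhat = xc.each_col() % cache.invstd;
  mat y = cache.xhat.each_row() % g.t();
  y.each_row() += b.t();
  return y;
}

static mat layernorm_bwd(const mat& dy, const vec& g, const LNCache& cache,
                         vec& dg, vec& db) {
  dg += arma::sum(dy % cache.xhat, 0).t();
  db += arma::sum(dy, 0).t();
  mat dxhat = dy.each_row() % g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() %= cache.invstd;
  return dx;
}

struct AttnCache {
  mat Q, K, V, headcat;
  std::vector<mat> A;   // per-head attention weights
};

// Multi-head attention. mask is additive (nq x nk), may be empty.
static mat mha_fwd(const mat& Xq, const mat& Xkv, const mat& WQ, const mat& WK,
                   const mat& WV, const mat& WO, int H, const mat& mask,
                   AttnCache& cache) {
  const uword w = WQ.n_cols;
  const uword dh = w / H;
  cache.Q = Xq * WQ;
  cache.K = Xkv * WK;
  cache.V = Xkv * WV;
  cache.headcat.set_size(Xq.n_rows, w);
  cache.A.assign(H, mat());
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < H; ++h) {
    arma::span hh(h * dh, (h + 1) * dh - 1);
    mat S = cache.Q.cols(hh) * cache.K.cols(hh).t() * scale;
    if (mask.n_elem) S += mask;
    cache.A[h] = softmax_rows(std::move(S));
    cache.headcat.cols(hh) = cache.A[h] * cache.V.cols(hh);
  }
  return cache.headcat * WO;
}

// Backward; accumulates parameter grads, returns (dXq, dXkv added into dXkv_acc).
static mat mha_bwd(const mat& dOut, const mat& Xq, const mat& Xkv,
                   const mat& WQ, const mat& WK, const mat& WV, const mat& WO,
                   int H, const AttnCache& cache,
                   mat& dWQ, mat& dWK, mat& dWV, mat& dWO, mat& dXkv_acc) {
  const uword w = WQ.n_cols;
  const uword dh = w / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  dWO += cache.headcat.t() * dOut;
  mat dHead = dOut * WO.t();
  mat dQ(arma::size(cache.Q), arma::fill::zeros);
  mat dK(arma::size(cache.K), arma::fill::zeros);
  mat dV(arma::size(cache.V), arma::fill::zeros);
  for (int h = 0; h < H; ++h) {
    arma::span hh(h * dh, (h + 1) * dh - 1);
    const mat& A = cache.A[h];
    mat dA = dHead.cols(hh) * cache.V.cols(hh).t();
    dV.cols(hh) += A.t() * dHead.cols(hh);
    vec rs = arma::sum(dA % A, 1);
    mat dS = A % (dA.each_col() - rs);
    dQ.cols(hh) += dS * cache.K.cols(hh) * scale;
    dK.cols(hh) += dS.t() * cache.Q.cols(hh) * scale;
  }
  dWQ += Xq.t() * dQ;
  dWK += Xkv.t() * dK;
  dWV += Xkv.t() * dV;
  dXkv_acc += dK * WK.t() + dV * WV.t();
  return dQ * WQ.t();
}

struct FFCache { mat H; };  // post-ReLU hidden

static mat ff_fwd(const mat& X, const mat& W1, const vec& b1, const mat& W2,
                  const vec& b2, FFCache& cache) {
  mat Hh = X * W1;
  Hh.each_row() += b1.t();
  Hh.transform([](double v) { return v > 0 ? v : 0.0; });
  cache.H = Hh;
  mat out = Hh * W2;
  out.each_row() += b2.t();
  return out;
}

static mat ff_bwd(const mat& dOut, const mat& X, const mat& W1, const mat& W2,
                  const FFCache& cache, mat& dW1, vec& db1, mat& dW2, vec& db2) {
  dW2 += cache.H.t() * dOut;
  db2 += arma::sum(dOut, 0).t();
  mat dH = dOut * W2.t();
  dH %= arma::conv_to<mat>::from(cache.H > 0);
  dW1 += X.t() * dH;
  db1 += arma::sum(dH, 0).t();
  return dH * W1.t();
}

// Inverted dropout mask (empty when rate == 0).
static mat dropout_mask(uword r, uword cls, double rate, std::mt19937_64& rng) {
  if (rate <= 0) return mat();
  std::uniform_real_distribution<double> U(0.0, 1.0);
  mat m(r, cls);
  const double keep = 1.0 - rate;
  for (uword j = 0; j < cls; ++j)
    for (uword i = 0; i < r; ++i)
      m(i, j) = U(rng) < keep ? 1.0 / keep : 0.0;
  return m;
}

// ------------------------------------------------------------ forward caches

struct EncLayerCache {
  mat Xin, attn_out, res1, X1, ff_out;   // X1 = post-ln1
  AttnCache attn; LNCache ln1, ln2; FFCache ff;
  mat drop_attn, drop_ffh;               // dropout masks (may be empty)
};

struct DecLayerCache {
  mat Xin, self_out, X1, cross_out, X2, ff_out;
  AttnCache self, cross; LNCache ln1, ln2, ln3; FFCache ff;
  mat drop_self, drop_cross, drop_ffh;
};

struct SeqCache {
  mat E0, EL, M, D0, Dlast, probs, Z;
  mat enc_mask, self_mask, cross_mask;
  std::vector<EncLayerCache> enc;
  std::vector<DecLayerCache> dec;
};

// All per-sequence computation is trimmed to the real length nr: pad
// positions are masked out of every attention anyway and carry no loss, so
// dropping them is exact and saves the wasted work. The organism-group
// memory row keeps the positional-encoding column of slot N+1 regardless
// of nr, matching the untrimmed layout.

static mat encoder_fwd(const arma::ivec& tok, int n_real, const Params& P,
                       const Cfg& c, SeqCache& S, const mat& e0_add,
                       double drop_rate, std::mt19937_64& rng) {
  const int nr = n_real;
  mat E0(nr, c.d);
  for (int i = 0; i < nr; ++i)
    E0.row(i) = P.Wa.col(tok[i] - 1).t() + P.WP.col(i).t();
  if (e0_add.n_elem) E0 += e0_add.rows(0, nr - 1);
  S.E0 = E0;
  mat no_mask;
  mat X = E0;
  S.enc.assign(c.Lenc, EncLayerCache());
  for (int l = 0; l < c.Lenc; ++l) {
    const EncLayer& L = P.enc[l];
    EncLayerCache& C = S.enc[l];
    C.Xin = X;
    C.attn_out = mha_fwd(X, X, L.WQ, L.WK, L.WV, L.WO, c.H, no_mask, C.attn);
    if (drop_rate > 0) {
      C.drop_attn = dropout_mask(nr, c.d, drop_rate, rng);
      C.attn_out %= C.drop_attn;
    }
    C.res1 = X + C.attn_out;
    C.X1 = layernorm_fwd(C.res1, L.ln1g, L.ln1b, C.ln1);
    C.ff_out = ff_fwd(C.X1, L.W1, L.b1, L.W2, L.b2, C.ff);
    if (drop_rate > 0) {
      C.drop_ffh = dropout_mask(nr, c.d, drop_rate, rng);
      C.ff_out %= C.drop_ffh;
    }
    X = layernorm_fwd(C.X1 + C.ff_out, L.ln2g, L.ln2b, C.ln2);
  }
  S.EL = X;
  return X;
}

static mat encoder_bwd(mat dX, const Params& P, const Cfg& c, SeqCache& S,
                       Grads& G, const arma::ivec& tok) {
  const int nr = dX.n_rows;
  for (int l = c.Lenc - 1; l >= 0; --l) {
    const EncLayer& L = P.enc[l];
    EncLayerCache& C = S.enc[l];
    EncLayer& gL = G.g.enc[l];
    mat dres2 = layernorm_bwd(dX, L.ln2g, C.ln2, gL.ln2g, gL.ln2b);
    mat dffout = dres2;
    if (C.drop_ffh.n_elem) dffout %= C.drop_ffh;
    mat dX1 = dres2 + ff_bwd(dffout, C.X1, L.W1, L.W2, C.ff, gL.W1, gL.b1, gL.W2, gL.b2);
    mat dres1 = layernorm_bwd(dX1, L.ln1g, C.ln1, gL.ln1g, gL.ln1b);
    mat dattn = dres1;
    if (C.drop_attn.n_elem) dattn %= C.drop_attn;
    mat dXkv(arma::size(C.Xin), arma::fill::zeros);
    mat dXq = mha_bwd(dattn, C.Xin, C.Xin, L.WQ, L.WK, L.WV, L.WO, c.H, C.attn,
                      gL.WQ, gL.WK, gL.WV, gL.WO, dXkv);
    dX = dres1 + dXq + dXkv;
  }
  // dX is now dE0 (nr x d)
  for (int i = 0; i < nr; ++i) {
    G.g.Wa.col(tok[i] - 1) += dX.row(i).t();
    G.g.WP.col(i) += dX.row(i).t();
  }
  return dX;
}

// memory over nr residues + group row; WS slots 1..nr for residues and the
// fixed slot N+1 for the group vector
static mat memory_fwd(const mat& EL, int group, const Params& P,
                      const Cfg& c, const mat& WS) {
  const int nr = EL.n_rows;
  mat M(nr + 1, c.dm());
  M(arma::span(0, nr - 1), arma::span(0, c.d - 1)) = EL;
  M(nr, arma::span(0, c.d - 1)) = P.WG.col(group - 1).t();
  M(arma::span(0, nr - 1), arma::span(c.d, c.dm() - 1)) = WS.cols(0, nr - 1).t();
  M(nr, arma::span(c.d, c.dm() - 1)) = WS.col(c.N).t();
  return M;
}

static mat decoder_fwd(const arma::ivec& lab_in, int n_real, const mat& M,
                       const Params& P, const Cfg& c, const mat& WS,
                       SeqCache& S, double drop_rate, std::mt19937_64& rng) {
  const int ns = n_real + 1;        // BOS + y_1..y_nr
  const int dm = c.dm();
  mat D0(ns, dm);
  for (int i = 0; i < ns; ++i) {
    D0(i, arma::span(0, c.d - 1)) = P.Wy.col(lab_in[i] - 1).t();
    D0(i, arma::span(c.d, dm - 1)) = WS.col(i).t();
  }
  S.D0 = D0;
  mat smask(ns, ns, arma::fill::zeros);
  for (int i = 0; i < ns; ++i)
    for (int j = i + 1; j < ns; ++j) smask(i, j) = NEG_MASK;
  S.self_mask = smask;
  mat no_mask;

  mat X = D0;
  S.dec.assign(c.Ldec, DecLayerCache());
  for (int l = 0; l < c.Ldec; ++l) {
    const DecLayer& L = P.dec[l];
    DecLayerCache& C = S.dec[l];
    C.Xin = X;
    C.self_out = mha_fwd(X, X, L.sWQ, L.sWK, L.sWV, L.sWO, c.H, S.self_mask, C.self);
    if (drop_rate > 0) {
      C.drop_self = dropout_mask(ns, dm, drop_rate, rng);
      C.self_out %= C.drop_self;
    }
    C.X1 = layernorm_fwd(X + C.self_out, L.ln1g, L.ln1b, C.ln1);
    C.cross_out = mha_fwd(C.X1, M, L.cWQ, L.cWK, L.cWV, L.cWO, c.H, no_mask, C.cross);
    if (drop_rate > 0) {
      C.drop_cross = dropout_mask(ns, dm, drop_rate, rng);
      C.cross_out %= C.drop_cross;
    }
    C.X2 = layernorm_fwd(C.X1 + C.cross_out, L.ln2g, L.ln2b, C.ln2);
    C.ff_out = ff_fwd(C.X2, L.W1, L.b1, L.W2, L.b2, C.ff);
    if (drop_rate > 0) {
      C.drop_ffh = dropout_mask(ns, dm, drop_rate, rng);
      C.ff_out %= C.drop_ffh;
    }
    X = layernorm_fwd(C.X2 + C.ff_out, L.ln3g, L.ln3b, C.ln3);
  }
  S.Dlast = X;
  return X;
}

// returns dD0 (first d cols feed dWy) and accumulates dM.
static mat decoder_bwd(mat dX, const mat& M, const Params& P, const Cfg& c,
                       SeqCache& S, Grads& G, mat& dM) {
  for (int l = c.Ldec - 1; l >= 0; --l) {
    const DecLayer& L = P.dec[l];
    DecLayerCache& C = S.dec[l];
    DecLayer& gL = G.g.dec[l];
    mat dres3 = layernorm_bwd(dX, L.ln3g, C.ln3, gL.ln3g, gL.ln3b);
    mat dffout = dres3;
    if (C.drop_ffh.n_elem) dffout %= C.drop_ffh;
    mat dX2 = dres3 + ff_bwd(dffout, C.X2, L.W1, L.W2, C.ff, gL.W1, gL.b1, gL.W2, gL.b2);
    mat dres2 = layernorm_bwd(dX2, L.ln2g, C.ln2, gL.ln2g, gL.ln2b);
    mat dcross = dres2;
    if (C.drop_cross.n_elem) dcross %= C.drop_cross;
    mat dX1 = dres2 + mha_bwd(dcross, C.X1, M, L.cWQ, L.cWK, L.cWV, L.cWO, c.H,
                              C.cross, gL.cWQ, gL.cWK, gL.cWV, gL.cWO, dM);
    mat dres1 = layernorm_bwd(dX1, L.ln1g, C.ln1, gL.ln1g, gL.ln1b);
    mat dself = dres1;
    if (C.drop_self.n_elem) dself %= C.drop_self;
    mat dXkv(arma::size(C.Xin), arma::fill::zeros);
    mat dXq = mha_bwd(dself, C.Xin, C.Xin, L.sWQ, L.sWK, L.sWV, L.sWO, c.H,
                      C.self, gL.sWQ, gL.sWK, gL.sWV, gL.sWO, dXkv);
    dX = dres1 + dXq + dXkv;
  }
  return dX;
}

// Output head: probability rows for positions 1..nr (Eq-7 style: decoder
// representation of the previous label concatenated with the one-hot of the
// current residue).
static mat output_fwd(const mat& Dlast, const arma::ivec& tok, const Params& P,
                      const Cfg& c, mat& Z) {
  const int dm = c.dm();
  const int nr = Dlast.n_rows - 1;
  Z.zeros(nr, dm + 21);
  Z.cols(0, dm - 1) = Dlast.rows(0, nr - 1);
  for (int k = 0; k < nr; ++k) Z(k, dm + tok[k] - 1) = 1.0;
  return softmax_rows(Z * P.WOout);
}

// Full teacher-forced forward for one sequence.
static void seq_forward(const arma::ivec& tok, int n_real, int group,
                        const arma::ivec& lab_in, const Params& P, const Cfg& c,
                        const mat& WS, SeqCache& S, const mat& e0_add,
                        double drop_rate, double drop_rate_enc,
                        std::mt19937_64& rng) {
  mat EL = encoder_fwd(tok, n_real, P, c, S, e0_add, drop_rate_enc, rng);
  S.M = memory_fwd(EL, group, P, c, WS);
  mat Dlast = decoder_fwd(lab_in, n_real, S.M, P, c, WS, S, drop_rate, rng);
  S.probs = output_fwd(Dlast, tok, P, c, S.Z);
}

// Backward from dlogits (nr x 8); returns dE0 (nr x d).
static mat seq_backward(const mat& dlogits, const arma::ivec& tok, int group,
                        const arma::ivec& lab_in, const Params& P, const Cfg& c,
                        SeqCache& S, Grads& G) {
  const int dm = c.dm();
  const int nr = dlogits.n_rows;
  G.g.WOout += S.Z.t() * dlogits;
  mat dZ = dlogits * P.WOout.t();
  mat dDlast(nr + 1, dm, arma::fill::zeros);
  dDlast.rows(0, nr - 1) = dZ.cols(0, dm - 1);
  mat dM(arma::size(S.M), arma::fill::zeros);
  mat dD0 = decoder_bwd(dDlast, S.M, P, c, S, G, dM);
  for (int i = 0; i <= nr; ++i)
    G.g.Wy.col(lab_in[i] - 1) += dD0(i, arma::span(0, c.d - 1)).t();
  G.g.WG.col(group - 1) += dM(nr, arma::span(0, c.d - 1)).t();
  mat dEL = dM(arma::span(0, nr - 1), arma::span(0, c.d - 1));
  return encoder_bwd(dEL, P, c, S, G, tok);
}

// softmax-cross-entropy gradient rows for the training loss
static mat ce_dlogits(const mat& probs, const arma::ivec& targets, int n_real,
                      const vec& w, double inv_norm, double& loss_acc) {
  mat dl(arma::size(probs), arma::fill::zeros);
  for (int k = 0; k < n_real; ++k) {
    int t = targets[k] - 1;
    double wk = w.n_elem ? w[t] : 1.0;
    loss_acc += -wk * std::log(std::max(probs(k, t), 1e-300));
    rowvec g = probs.row(k) * wk;
    g[t] -= wk;
    dl.row(k) = g * inv_norm;
  }
  return dl;
}

// ------------------------------------------------------------------ exports

// In-place Adam step on flattened parameter/moment vectors. The caller owns
// the buffers exclusively (optimizer state), so mutating them is safe and
// avoids per-step copies.
// [[Rcpp::export]]
double cpp_adam_step(NumericVector flat, NumericVector g, NumericVector m,
                     NumericVector v, NumericVector lr, int t,
                     double beta1, double beta2, double eps) {
  const R_xlen_t n = flat.size();
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  double gnorm2 = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    gnorm2 += gi * gi;
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    flat[i] -= lr[i] * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
  return std::sqrt(gnorm2);
}

// [[Rcpp::export]]
arma::mat cpp_sinusoidal_pe(int dS, int N) {
  if (dS % 2 != 0) stop("dS must be even");
  return make_ws(dS, N);
}

// [[Rcpp::export]]
List cpp_encode(const IntegerMatrix& tokens, const IntegerVector& n_real,
                const List& params, const List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  std::mt19937_64 rng(0);
  List out(tokens.nrow());
  for (int b = 0; b < tokens.nrow(); ++b) {
    arma::ivec tok(c.N);
    for (int i = 0; i < c.N; ++i) tok[i] = tokens(b, i);
    SeqCache S;
    mat EL = encoder_fwd(tok, n_real[b], P, c, S, mat(), 0.0, rng);
    mat full(c.N, c.d, arma::fill::zeros);   // pad rows stay zero
    full.rows(0, n_real[b] - 1) = EL;
    out[b] = full;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_assemble_memory(const arma::mat& EL, int group, const List& params,
                              const List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  if ((int)EL.n_rows != c.N || (int)EL.n_cols != c.d) stop("EL must be N x d");
  if (group < 1 || group > 4) stop("unknown organism group id");
  mat WS = make_ws(c.dS, c.N);
  return memory_fwd(EL, group, P, c, WS);
}

// Teacher-forced probability rows (no dropout). e0_add optionally perturbs
// the initial embedding E0 (used by finite-difference saliency checks).
// [[Rcpp::export]]
arma::mat cpp_tf_probs(const IntegerVector& tokens, int n_real, int group,
                       const IntegerVector& labels_in, const List& params,
                       const List& cfg, Nullable<NumericMatrix> e0_add = R_NilValue) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  if (labels_in[0] != 9) stop("decoder input must begin with BOS");
  mat WS = make_ws(c.dS, c.N);
  arma::ivec tok(c.N), lin(c.N + 1);
  for (int i = 0; i < c.N; ++i) tok[i] = tokens[i];
  for (int i = 0; i <= c.N; ++i) lin[i] = labels_in[i];
  mat e0;
  if (e0_add.isNotNull()) e0 = as<mat>(e0_add.get());
  SeqCache S;
  std::mt19937_64 rng(0);
  seq_forward(tok, n_real, group, lin, P, c, WS, S, e0, 0.0, 0.0, rng);
  mat full(c.N, 8, arma::fill::value(1.0 / 8));   // pad rows: uninformative
  full.rows(0, n_real - 1) = S.probs;
  return full;
}

// Training/eval loss and gradients over a batch.
// [[Rcpp::export]]
List cpp_loss_grad(const IntegerMatrix& tokens, const IntegerVector& n_real,
                   const IntegerVector& groups, const IntegerMatrix& labels_in,
                   const IntegerMatrix& targets, const List& params,
                   const List& cfg, bool want_grads, bool train_mode,
                   int dropout_seed, Nullable<NumericVector> class_weights = R_NilValue) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  mat WS = make_ws(c.dS, c.N);
  const int B = tokens.nrow();
  vec w;
  if (class_weights.isNotNull()) w = as<vec>(class_weights.get());
  double total_pos = 0;
  for (int b = 0; b < B; ++b) total_pos += n_real[b];
  const double inv_norm = 1.0 / total_pos;
  double loss = 0;
  Grads G(P);
  std::mt19937_64 rng((uint64_t)dropout_seed);
  const double dr = train_mode ? c.dropout : 0.0;
  const double dre = train_mode ? c.dropout_enc : 0.0;
  for (int b = 0; b < B; ++b) {
    arma::ivec tok(c.N), lin(c.N + 1), tgt(c.N);
    for (int i = 0; i < c.N; ++i) { tok[i] = tokens(b, i); tgt[i] = targets(b, i); }
    for (int i = 0; i <= c.N; ++i) lin[i] = labels_in(b, i);
    if (lin[0] != 9) stop("decoder input must begin with BOS");
    SeqCache S;
    seq_forward(tok, n_real[b], groups[b], lin, P, c, WS, S, mat(), dr, dre, rng);
    mat dl = ce_dlogits(S.probs, tgt, n_real[b], w, inv_norm, loss);
    if (want_grads) seq_backward(dl, tok, groups[b], lin, P, c, S, G);
  }
  List out;
  out["loss"] = loss * inv_norm;
  out["n_positions"] = total_pos;
  if (want_grads) out["grads"] = grads_to_list(G, c);
  return out;
}

// Gradient of the probability of `target_label` (1..8) at position
// `target_pos` (1..N) with respect to E0, conditioning the decoder on
// `labels_in` (teacher-forced; at analysis time these are the model's own
// predictions). Returns the N x d gradient matrix.
// [[Rcpp::export]]
arma::mat cpp_input_grad(const IntegerVector& tokens, int n_real, int group,
                         const IntegerVector& labels_in, int target_pos,
                         int target_label, const List& params, const List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  if (target_pos < 1 || target_pos > n_real) stop("target_pos outside sequence");
  mat WS = make_ws(c.dS, c.N);
  arma::ivec tok(c.N), lin(c.N + 1);
  for (int i = 0; i < c.N; ++i) tok[i] = tokens[i];
  for (int i = 0; i <= c.N; ++i) lin[i] = labels_in[i];
  if (lin[0] != 9) stop("decoder input must begin with BOS");
  SeqCache S;
  std::mt19937_64 rng(0);
  seq_forward(tok, n_real, group, lin, P, c, WS, S, mat(), 0.0, 0.0, rng);
  // d p_t / d logits = p_t * (e_t - p)
  mat dl(arma::size(S.probs), arma::fill::zeros);
  int k = target_pos - 1, t = target_label - 1;
  double pt = S.probs(k, t);
  rowvec g = -pt * S.probs.row(k);
  g[t] += pt;
  dl.row(k) = g;
  Grads G(P);
  return seq_backward(dl, tok, group, lin, P, c, S, G);
}

// --------------------------------------------------- KV-cached greedy decode

// [[Rcpp::export]]
List cpp_greedy_decode(const IntegerMatrix& tokens, const IntegerVector& n_real,
                       const IntegerVector& groups, const List& params,
                       const List& cfg) {
  Cfg c = parse_cfg(cfg);
  Params P = parse_params(params, c);
  mat WS = make_ws(c.dS, c.N);
  const int B = tokens.nrow();
  const int dm = c.dm();
  const int dh = dm / c.H;
  const double scale = 1.0 / std::sqrt((double)dh);
  std::mt19937_64 rng(0);
  IntegerMatrix out_labels(B, c.N);
  List out_probs(B);

  for (int b = 0; b < B; ++b) {
    const int nr = n_real[b];
    arma::ivec tok(c.N);
    for (int i = 0; i < c.N; ++i) tok[i] = tokens(b, i);
    SeqCache S;
    mat EL = encoder_fwd(tok, nr, P, c, S, mat(), 0.0, rng);
    mat M = memory_fwd(EL, groups[b], P, c, WS);
    // cross-attention K,V per layer (memory has nr + 1 rows, all attendable)
    std::vector<mat> cK(c.Ldec), cV(c.Ldec);
    for (int l = 0; l < c.Ldec; ++l) {
      cK[l] = M * P.dec[l].cWK;
      cV[l] = M * P.dec[l].cWV;
    }
    std::vector<mat> sK(c.Ldec), sV(c.Ldec);   // grown row by row
    for (int l = 0; l < c.Ldec; ++l) { sK[l].set_size(nr + 1, dm); sV[l].set_size(nr + 1, dm); }

    mat probs(nr, 8);
    int prev_label_tok = 9;                    // BOS
    for (int p = 0; p < nr; ++p) {
      // stream position p holds label token y_p (p = 0 -> BOS)
      rowvec x(dm);
      x.subvec(0, c.d - 1) = P.Wy.col(prev_label_tok - 1).t();
      x.subvec(c.d, dm - 1) = WS.col(p).t();
      for (int l = 0; l < c.Ldec; ++l) {
        const DecLayer& L = P.dec[l];
        // self-attention over cached positions 0..p
        rowvec q = x * L.sWQ;
        sK[l].row(p) = x * L.sWK;
        sV[l].row(p) = x * L.sWV;
        rowvec head(dm);
        for (int h = 0; h < c.H; ++h) {
          arma::span hh(h * dh, (h + 1) * dh - 1);
          rowvec s = q.cols(hh) * sK[l](arma::span(0, p), hh).t() * scale;
          s -= s.max();
          rowvec a = arma::exp(s);
          a /= arma::accu(a);
          head.cols(hh) = a * sV[l](arma::span(0, p), hh);
        }
        rowvec attn = head * L.sWO;
        // post-residual layer norm on the single row
        auto ln_row = [&](rowvec r, const vec& g, const vec& bb) {
          double mu = arma::mean(r);
          r -= mu;
          double sd = std::sqrt(arma::mean(arma::square(r)) + LN_EPS);
          return rowvec((r / sd) % g.t() + bb.t());
        };
        rowvec x1 = ln_row(x + attn, L.ln1g, L.ln1b);
        rowvec q2 = x1 * L.cWQ;
        rowvec head2(dm);
        for (int h = 0; h < c.H; ++h) {
          arma::span hh(h * dh, (h + 1) * dh - 1);
          rowvec s = q2.cols(hh) * cK[l].cols(hh).t() * scale;
          s -= s.max();
          rowvec a = arma::exp(s);
          a /= arma::accu(a);
          head2.cols(hh) = a * cV[l].cols(hh);
        }
        rowvec x2 = ln_row(x1 + head2 * L.cWO, L.ln2g, L.ln2b);
        rowvec hidden = x2 * L.W1 + L.b1.t();
        hidden.transform([](double v) { return v > 0 ? v : 0.0; });
        rowvec ff = hidden * L.W2 + L.b2.t();
        x = ln_row(x2 + ff, L.ln3g, L.ln3b);
      }
      // predict label y_{p+1} from this representation + one-hot of residue p+1
      rowvec z(dm + 21, arma::fill::zeros);
      z.subvec(0, dm - 1) = x;
      z[dm + tok[p] - 1] = 1.0;
      rowvec logit = z * P.WOout;
      logit -= logit.max();
      rowvec pr = arma::exp(logit);
      pr /= arma::accu(pr);
      probs.row(p) = pr;
      int best = 0;
      for (int j = 1; j < 8; ++j) if (pr[j] > pr[best]) best = j;  // ties -> lowest id
      out_labels(b, p) = best + 1;
      prev_label_tok = best + 1;
    }
    for (int p = nr; p < c.N; ++p) out_labels(b, p) = NA_INTEGER;
    out_probs[b] = probs;
  }
  return List::create(_["labels"] = out_labels, _["probs"] = out_probs);
}
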