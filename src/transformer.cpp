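// Compact encoder-decoder Transformer for short-phrase translation,
// trained per-sequence with Adam.  Pre-layer-norm residual blocks,
// sinusoidal positions, shared source/target embedding, label smoothing.
// Deterministic given the seed: all randomness flows through one mt19937.
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double NEG_INF = -1e30;

struct Lin { mat W; vec b; };
struct LNp { vec g; vec b; };
struct Attn { Lin q, k, v, o; };
struct EncLayer { LNp ln1; Attn att; LNp ln2; Lin f1, f2; };
struct DecLayer { LNp ln1; Attn self; LNp ln2; Attn cross; LNp ln3; Lin f1, f2; };

struct Model {
  int V, d, H, L, F, maxlen;
  mat E;                       // d x V shared embedding
  std::vector<EncLayer> enc;
  std::vector<DecLayer> dec;
  LNp lnenc, lnf;
  Lin out;                     // V x d
  mat P;                       // d x maxlen sinusoidal positions (fixed)
};

// ---- parameter enumeration (fixed order for flatten/Adam) ----
struct Slot { double* p; size_t n; };

static void add_lin(std::vector<Slot>& s, Lin& l) {
  s.push_back({l.W.memptr(), l.W.n_elem});
  s.push_back({l.b.memptr(), l.b.n_elem});
}
static void add_ln(std::vector<Slot>& s, LNp& l) {
  s.push_back({l.g.memptr(), l.g.n_elem});
  s.push_back({l.b.memptr(), l.b.n_elem});
}
static void add_attn(std::vector<Slot>& s, Attn& a) {
  add_lin(s, a.q); add_lin(s, a.k); add_lin(s, a.v); add_lin(s, a.o);
}
static std::vector<Slot> slots(Model& m) {
  std::vector<Slot> s;
  s.push_back({m.E.memptr(), m.E.n_elem});
  for (auto& l : m.enc) {
    add_ln(s, l.ln1); add_attn(s, l.att); add_ln(s, l.ln2);
    add_lin(s, l.f1); add_lin(s, l.f2);
  }
  add_ln(s, m.lnenc);
  for (auto& l : m.dec) {
    add_ln(s, l.ln1); add_attn(s, l.self); add_ln(s, l.ln2);
    add_attn(s, l.cross); add_ln(s, l.ln3);
    add_lin(s, l.f1); add_lin(s, l.f2);
  }
  add_ln(s, m.lnf);
  add_lin(s, m.out);
  return s;
}
static size_t n_params(Model& m) {
  size_t n = 0;
  for (auto& s : slots(m)) n += s.n;
  return n;
}

static void shape_model(Model& m, int V, int d, int H, int L, int F, int maxlen) {
  m.V = V; m.d = d; m.H = H; m.L = L; m.F = F; m.maxlen = maxlen;
  m.E.set_size(d, V);
  m.enc.resize(L); m.dec.resize(L);
  auto lin = [](Lin& l, int nout, int nin) { l.W.set_size(nout, nin); l.b.set_size(nout); };
  auto lnp = [d](LNp& l) { l.g.set_size(d); l.b.set_size(d); };
  auto att = [&](Attn& a) { lin(a.q, d, d); lin(a.k, d, d); lin(a.v, d, d); lin(a.o, d, d); };
  for (auto& l : m.enc) {
    lnp(l.ln1); att(l.att); lnp(l.ln2); lin(l.f1, F, d); lin(l.f2, d, F);
  }
  lnp(m.lnenc);
  for (auto& l : m.dec) {
    lnp(l.ln1); att(l.self); lnp(l.ln2); att(l.cross); lnp(l.ln3);
    lin(l.f1, F, d); lin(l.f2, d, F);
  }
  lnp(m.lnf);
  lin(m.out, V, d);
  m.P.set_size(d, maxlen);
  for (int pos = 0; pos < maxlen; ++pos)
    for (int i = 0; i < d; ++i) {
      double angle = pos / std::pow(10000.0, 2.0 * (i / 2) / d);
      m.P(i, pos) = (i % 2 == 0) ? std::sin(angle) : std::cos(angle);
    }
}

static void init_model(Model& m, std::mt19937& rng) {
  std::normal_distribution<double> nd(0.0, 0.02);
  auto fill_xavier = [&](mat& W) {
    double lim = std::sqrt(6.0 / (W.n_rows + W.n_cols));
    std::uniform_real_distribution<double> ud(-lim, lim);
    for (size_t i = 0; i < W.n_elem; ++i) W(i) = ud(rng);
  };
  for (size_t i = 0; i < m.E.n_elem; ++i) m.E(i) = nd(rng);
  auto init_lin = [&](Lin& l) { fill_xavier(l.W); l.b.zeros(); };
  auto init_ln = [](LNp& l) { l.g.ones(); l.b.zeros(); };
  auto init_attn = [&](Attn& a) { init_lin(a.q); init_lin(a.k); init_lin(a.v); init_lin(a.o); };
  for (auto& l : m.enc) {
    init_ln(l.ln1); init_attn(l.att); init_ln(l.ln2); init_lin(l.f1); init_lin(l.f2);
  }
  init_ln(m.lnenc);
  for (auto& l : m.dec) {
    init_ln(l.ln1); init_attn(l.self); init_ln(l.ln2); init_attn(l.cross); init_ln(l.ln3);
    init_lin(l.f1); init_lin(l.f2);
  }
  init_ln(m.lnf);
  init_lin(m.out);
}

static void zero_model(Model& g) {
  for (auto& s : slots(g)) std::fill(s.p, s.p + s.n, 0.0);
}

static void flatten(Model& m, double* out) {
  for (auto& s : slots(m)) { std::copy(s.p, s.p + s.n, out); out += s.n; }
}
static void unflatten(Model& m, const double* in) {
  for (auto& s : slots(m)) { std::copy(in, in + s.n, s.p); in += s.n; }
}

// ---- layers ----
struct LNCache { mat xhat; rowvec invsd; };

static mat ln_fwd(const LNp& p, const mat& X, LNCache& c) {
  const double eps = 1e-5;
  rowvec mu = arma::mean(X, 0);
  mat cent = X.each_row() - mu;
  rowvec var = arma::mean(arma::square(cent), 0);
  c.invsd = 1.0 / arma::sqrt(var + eps);
  c.xhat = cent.each_row() % c.invsd;
  mat Y = c.xhat.each_col() % p.g;
  Y.each_col() += p.b;
  return Y;
}

static void ln_bwd(const LNp& p, LNp& g, const LNCache& c, const mat& dY, mat& dX) {
  g.g += arma::sum(dY % c.xhat, 1);
  g.b += arma::sum(dY, 1);
  mat dxh = dY.each_col() % p.g;
  rowvec m1 = arma::mean(dxh, 0);
  rowvec m2 = arma::mean(dxh % c.xhat, 0);
  mat t = dxh;
  t.each_row() -= m1;
  t -= c.xhat.each_row() % m2;
  dX += t.each_row() % c.invsd;
}

static mat lin_fwd(const Lin& p, const mat& X) {
  mat Y = p.W * X;
  Y.each_col() += p.b;
  return Y;
}
static void lin_bwd(const Lin& p, Lin& g, const mat& X, const mat& dY, mat& dX) {
  g.W += dY * X.t();
  g.b += arma::sum(dY, 1);
  dX += p.W.t() * dY;
}

struct AttnCache {
  mat Xq, Xm, Q, K, Vv, O;
  std::vector<mat> A;  // per-head Lm x Lq
};

static mat attn_fwd(const Attn& p, const mat& Xq, const mat& Xm, bool causal,
                    int H, AttnCache& c) {
  int d = Xq.n_rows, dh = d / H;
  c.Xq = Xq; c.Xm = Xm;
  c.Q = lin_fwd(p.q, Xq);
  c.K = lin_fwd(p.k, Xm);
  c.Vv = lin_fwd(p.v, Xm);
  int Lq = Xq.n_cols, Lm = Xm.n_cols;
  c.O.set_size(d, Lq);
  c.A.assign(H, mat());
  double scale = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < H; ++h) {
    mat Qh = c.Q.rows(h * dh, (h + 1) * dh - 1);
    mat Kh = c.K.rows(h * dh, (h + 1) * dh - 1);
    mat Vh = c.Vv.rows(h * dh, (h + 1) * dh - 1);
    mat S = (Kh.t() * Qh) * scale;  // Lm x Lq
    if (causal)
      for (int j = 0; j < Lq; ++j)
        for (int i = j + 1; i < Lm; ++i) S(i, j) = NEG_INF;
    // softmax over rows within each column
    rowvec mx = arma::max(S, 0);
    S.each_row() -= mx;
    S = arma::exp(S);
    rowvec den = arma::sum(S, 0);
    S.each_row() /= den;
    c.A[h] = S;
    c.O.rows(h * dh, (h + 1) * dh - 1) = Vh * S;
  }
  return lin_fwd(p.o, c.O);
}

static void attn_bwd(const Attn& p, Attn& g, const AttnCache& c, const mat& dOut,
                     int H, mat& dXq, mat& dXm) {
  int d = c.Q.n_rows, dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);
  mat dO(d, c.O.n_cols, arma::fill::zeros);
  lin_bwd(p.o, g.o, c.O, dOut, dO);
  mat dQ(arma::size(c.Q), arma::fill::zeros);
  mat dK(arma::size(c.K), arma::fill::zeros);
  mat dV(arma::size(c.Vv), arma::fill::zeros);
  for (int h = 0; h < H; ++h) {
    mat Qh = c.Q.rows(h * dh, (h + 1) * dh - 1);
    mat Kh = c.K.rows(h * dh, (h + 1) * dh - 1);
    mat Vh = c.Vv.rows(h * dh, (h + 1) * dh - 1);
    mat dOh = dO.rows(h * dh, (h + 1) * dh - 1);
    const mat& A = c.A[h];
    dV.rows(h * dh, (h + 1) * dh - 1) = dOh * A.t();
    mat dA = Vh.t() * dOh;  // Lm x Lq
    rowvec dot = arma::sum(A % dA, 0);
    mat dS = A % (dA.each_row() - dot);
    dQ.rows(h * dh, (h + 1) * dh - 1) = (Kh * dS) * scale;
    dK.rows(h * dh, (h + 1) * dh - 1) = (Qh * dS.t()) * scale;
  }
  lin_bwd(p.q, g.q, c.Xq, dQ, dXq);
  lin_bwd(p.k, g.k, c.Xm, dK, dXm);
  lin_bwd(p.v, g.v, c.Xm, dV, dXm);
}

struct FFNCache { mat Xin, H1; };
static mat ffn_fwd(const Lin& f1, const Lin& f2, const mat& X, FFNCache& c) {
  c.Xin = X;
  c.H1 = lin_fwd(f1, X);
  c.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  return lin_fwd(f2, c.H1);
}
static void ffn_bwd(const Lin& f1, const Lin& f2, Lin& g1, Lin& g2,
                    const FFNCache& c, const mat& dY, mat& dX) {
  mat dH1(arma::size(c.H1), arma::fill::zeros);
  lin_bwd(f2, g2, c.H1, dY, dH1);
  dH1 %= arma::conv_to<mat>::from(c.H1 > 0);
  lin_bwd(f1, g1, c.Xin, dH1, dX);
}

// ---- encoder / decoder forward with caches ----
struct EncCache {
  mat X0;
  std::vector<LNCache> ln1, ln2;
  std::vector<AttnCache> att;
  std::vector<FFNCache> ffn;
  std::vector<mat> Xres1, Xres2;  // inputs of the two residual blocks
  LNCache lnenc;
  mat Mem;
};

static mat embed(const Model& m, const std::vector<int>& ids) {
  int Lx = ids.size();
  mat X(m.d, Lx);
  double s = std::sqrt((double)m.d);
  for (int t = 0; t < Lx; ++t) X.col(t) = m.E.col(ids[t]) * s + m.P.col(t);
  return X;
}

static void enc_fwd(const Model& m, const std::vector<int>& src, EncCache& c) {
  c.X0 = embed(m, src);
  int L = m.L;
  c.ln1.resize(L); c.ln2.resize(L); c.att.resize(L); c.ffn.resize(L);
  c.Xres1.resize(L); c.Xres2.resize(L);
  mat X = c.X0;
  for (int l = 0; l < L; ++l) {
    c.Xres1[l] = X;
    mat Xn = ln_fwd(m.enc[l].ln1, X, c.ln1[l]);
    X += attn_fwd(m.enc[l].att, Xn, Xn, false, m.H, c.att[l]);
    c.Xres2[l] = X;
    mat Xm2 = ln_fwd(m.enc[l].ln2, X, c.ln2[l]);
    X += ffn_fwd(m.enc[l].f1, m.enc[l].f2, Xm2, c.ffn[l]);
  }
  c.Mem = ln_fwd(m.lnenc, X, c.lnenc);
}

struct DecCache {
  mat Y0;
  std::vector<LNCache> ln1, ln2, ln3;
  std::vector<AttnCache> self, cross;
  std::vector<FFNCache> ffn;
  std::vector<mat> Yres1, Yres2, Yres3;
  LNCache lnf;
  mat Yfin, Logits;
};

static void dec_fwd(const Model& m, const mat& Mem, const std::vector<int>& tgt_in,
                    DecCache& c) {
  c.Y0 = embed(m, tgt_in);
  int L = m.L;
  c.ln1.resize(L); c.ln2.resize(L); c.ln3.resize(L);
  c.self.resize(L); c.cross.resize(L); c.ffn.resize(L);
  c.Yres1.resize(L); c.Yres2.resize(L); c.Yres3.resize(L);
  mat Y = c.Y0;
  for (int l = 0; l < L; ++l) {
    c.Yres1[l] = Y;
    mat Yn = ln_fwd(m.dec[l].ln1, Y, c.ln1[l]);
    Y += attn_fwd(m.dec[l].self, Yn, Yn, true, m.H, c.self[l]);
    c.Yres2[l] = Y;
    mat Yc = ln_fwd(m.dec[l].ln2, Y, c.ln2[l]);
    Y += attn_fwd(m.dec[l].cross, Yc, Mem, false, m.H, c.cross[l]);
    c.Yres3[l] = Y;
    mat Yf = ln_fwd(m.dec[l].ln3, Y, c.ln3[l]);
    Y += ffn_fwd(m.dec[l].f1, m.dec[l].f2, Yf, c.ffn[l]);
  }
  c.Yfin = ln_fwd(m.lnf, Y, c.lnf);
  c.Logits = lin_fwd(m.out, c.Yfin);
}

// Cross-entropy with label smoothing; returns mean loss per token and
// writes dLogits.
static double ce_loss(const mat& logits, const std::vector<int>& tgt_out,
                      double eps, mat& dLogits) {
  int T = tgt_out.size(), V = logits.n_rows;
  mat P = logits;
  rowvec mx = arma::max(P, 0);
  P.each_row() -= mx;
  P = arma::exp(P);
  rowvec den = arma::sum(P, 0);
  P.each_row() /= den;
  double loss = 0.0;
  dLogits = P;
  for (int t = 0; t < T; ++t) {
    vec logp = arma::log(P.col(t) + 1e-12);
    loss += -(1.0 - eps) * logp(tgt_out[t]) - (eps / V) * arma::accu(logp);
    dLogits(tgt_out[t], t) -= (1.0 - eps);
    dLogits.col(t) -= eps / V;
  }
  dLogits /= T;
  return loss / T;
}

// Full backward pass for one pair.  Gradients accumulate into g.
static void backward(const Model& m, Model& g, const std::vector<int>& src,
                     const std::vector<int>& tgt_in, EncCache& ec, DecCache& dc,
                     const mat& dLogits) {
  int L = m.L;
  double sd = std::sqrt((double)m.d);
  mat dYfin(arma::size(dc.Yfin), arma::fill::zeros);
  lin_bwd(m.out, g.out, dc.Yfin, dLogits, dYfin);
  mat dY(arma::size(dc.Y0), arma::fill::zeros);
  ln_bwd(m.lnf, g.lnf, dc.lnf, dYfin, dY);
  mat dMem(arma::size(ec.Mem), arma::fill::zeros);
  for (int l = L - 1; l >= 0; --l) {
    // ffn block
    mat dYf(arma::size(dY), arma::fill::zeros);
    ffn_bwd(m.dec[l].f1, m.dec[l].f2, g.dec[l].f1, g.dec[l].f2, dc.ffn[l], dY, dYf);
    ln_bwd(m.dec[l].ln3, g.dec[l].ln3, dc.ln3[l], dYf, dY);
    // cross-attention block
    mat dYc(arma::size(dY), arma::fill::zeros);
    attn_bwd(m.dec[l].cross, g.dec[l].cross, dc.cross[l], dY, m.H, dYc, dMem);
    ln_bwd(m.dec[l].ln2, g.dec[l].ln2, dc.ln2[l], dYc, dY);
    // masked self-attention block
    mat dYs(arma::size(dY), arma::fill::zeros);
    attn_bwd(m.dec[l].self, g.dec[l].self, dc.self[l], dY, m.H, dYs, dYs);
    ln_bwd(m.dec[l].ln1, g.dec[l].ln1, dc.ln1[l], dYs, dY);
  }
  for (size_t t = 0; t < tgt_in.size(); ++t) g.E.col(tgt_in[t]) += dY.col(t) * sd;
  // encoder
  mat dX(arma::size(ec.X0), arma::fill::zeros);
  ln_bwd(m.lnenc, g.lnenc, ec.lnenc, dMem, dX);
  for (int l = L - 1; l >= 0; --l) {
    mat dXf(arma::size(dX), arma::fill::zeros);
    ffn_bwd(m.enc[l].f1, m.enc[l].f2, g.enc[l].f1, g.enc[l].f2, ec.ffn[l], dX, dXf);
    ln_bwd(m.enc[l].ln2, g.enc[l].ln2, ec.ln2[l], dXf, dX);
    mat dXs(arma::size(dX), arma::fill::zeros);
    attn_bwd(m.enc[l].att, g.enc[l].att, ec.att[l], dX, m.H, dXs, dXs);
    ln_bwd(m.enc[l].ln1, g.enc[l].ln1, ec.ln1[l], dXs, dX);
  }
  for (size_t t = 0; t < src.size(); ++t) g.E.col(src[t]) += dX.col(t) * sd;
}

// ---- Adam ----
struct AdamState { std::vector<double> m1, m2; long step = 0; };

static void adam_step(Model& m, Model& g, AdamState& st, double lr, double clip) {
  auto ps = slots(m), gs = slots(g);
  size_t n = 0;
  for (auto& s : ps) n += s.n;
  if (st.m1.empty()) { st.m1.assign(n, 0.0); st.m2.assign(n, 0.0); }
  double norm2 = 0.0;
  for (auto& s : gs) for (size_t i = 0; i < s.n; ++i) norm2 += s.p[i] * s.p[i];
  double scale = 1.0;
  double norm = std::sqrt(norm2);
  if (clip > 0 && norm > clip) scale = clip / norm;
  st.step += 1;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double bc1 = 1.0 - std::pow(b1, (double)st.step);
  double bc2 = 1.0 - std::pow(b2, (double)st.step);
  size_t off = 0;
  for (size_t k = 0; k < ps.size(); ++k) {
    for (size_t i = 0; i < ps[k].n; ++i) {
      double gr = gs[k].p[i] * scale;
      st.m1[off + i] = b1 * st.m1[off + i] + (1 - b1) * gr;
      st.m2[off + i] = b2 * st.m2[off + i] + (1 - b2) * gr * gr;
      double mhat = st.m1[off + i] / bc1;
      double vhat = st.m2[off + i] / bc2;
      ps[k].p[i] -= lr * mhat / (std::sqrt(vhat) + eps);
    }
    off += ps[k].n;
  }
}

static std::vector<int> iv_to_std(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_nmt_train(List src, List tgt, int vocab, int d, int heads, int layers,
                   int ffn, int max_len, int epochs, double lr,
                   double label_smooth, double clip, int seed, bool verbose,
                   Nullable<NumericVector> init_params = R_NilValue) {
  int n = src.size();
  Model m, g;
  shape_model(m, vocab, d, heads, layers, ffn, max_len);
  shape_model(g, vocab, d, heads, layers, ffn, max_len);
  std::mt19937 rng(seed);
  if (init_params.isNotNull()) {
    NumericVector ip(init_params);
    unflatten(m, REAL(ip));
  } else {
    init_model(m, rng);
  }
  std::vector<std::vector<int>> S(n), Tin(n), Tout(n);
  const int BOS = 1, EOS = 2;
  for (int i = 0; i < n; ++i) {
    S[i] = iv_to_std(src[i]);
    std::vector<int> t = iv_to_std(tgt[i]);
    Tin[i].push_back(BOS);
    for (int x : t) Tin[i].push_back(x);
    Tout[i] = t;
    Tout[i].push_back(EOS);
  }
  AdamState st;
  NumericVector epoch_loss(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0.0;
    for (int idx : order) {
      EncCache ec; DecCache dc;
      enc_fwd(m, S[idx], ec);
      dec_fwd(m, ec.Mem, Tin[idx], dc);
      mat dLogits;
      tot += ce_loss(dc.Logits, Tout[idx], label_smooth, dLogits);
      zero_model(g);
      backward(m, g, S[idx], Tin[idx], ec, dc, dLogits);
      adam_step(m, g, st, lr, clip);
    }
    epoch_loss[e] = tot / n;
    if (verbose) Rcpp::Rcout << "epoch " << (e + 1) << " loss " << epoch_loss[e] << "\n";
    Rcpp::checkUserInterrupt();
  }
  NumericVector flat(n_params(m));
  flatten(m, REAL(flat));
  return List::create(_["params"] = flat, _["loss"] = epoch_loss);
}

struct Beam {
  std::vector<int> toks;  // decoder input, starts with BOS
  double logp;
  bool done;
};

// [[Rcpp::export]]
List cpp_nmt_decode(NumericVector params, List src, int vocab, int d, int heads,
                    int layers, int ffn, int max_len, int beam_size, int k) {
  Model m;
  shape_model(m, vocab, d, heads, layers, ffn, max_len);
  unflatten(m, REAL(params));
  const int BOS = 1, EOS = 2;
  int n = src.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> s = iv_to_std(src[i]);
    EncCache ec;
    enc_fwd(m, s, ec);
    std::vector<Beam> beams = {{{BOS}, 0.0, false}};
    std::vector<Beam> finished;
    for (int step = 0; step < max_len - 1; ++step) {
      std::vector<Beam> expansions;
      bool any_live = false;
      for (const Beam& b : beams) {
        if (b.done) { expansions.push_back(b); continue; }
        any_live = true;
        DecCache dc;
        dec_fwd(m, ec.Mem, b.toks, dc);
        vec logits = dc.Logits.col(dc.Logits.n_cols - 1);
        double mx = logits.max();
        vec lp = logits - (mx + std::log(arma::accu(arma::exp(logits - mx))));
        // top beam_size continuations of this beam
        arma::uvec ord = arma::sort_index(lp, "descend");
        for (int j = 0; j < beam_size && j < (int)ord.n_elem; ++j) {
          Beam nb = b;
          int tok = (int)ord[j];
          nb.toks.push_back(tok);
          nb.logp += lp(tok);
          nb.done = (tok == EOS);
          expansions.push_back(nb);
        }
      }
      if (!any_live) break;
      std::stable_sort(expansions.begin(), expansions.end(),
                       [](const Beam& a, const Beam& b) { return a.logp > b.logp; });
      if ((int)expansions.size() > beam_size) expansions.resize(beam_size);
      beams = expansions;
      bool all_done = true;
      for (const Beam& b : beams) if (!b.done) { all_done = false; break; }
      if (all_done) break;
    }
    for (Beam& b : beams) {
      if (!b.done) { b.toks.push_back(EOS); b.done = true; }
      finished.push_back(b);
    }
    // rank by length-normalised log-probability
    auto score = [](const Beam& b) {
      int len = (int)b.toks.size() - 1;  // generated tokens incl. EOS
      return b.logp / std::max(1, len);
    };
    std::stable_sort(finished.begin(), finished.end(),
                     [&](const Beam& a, const Beam& b) { return score(a) > score(b); });
    int keep = std::min((int)finished.size(), std::max(beam_size, k));
    List toks(keep);
    NumericVector scores(keep);
    for (int j = 0; j < keep; ++j) {
      const Beam& b = finished[j];
      std::vector<int> body;
      for (size_t t = 1; t < b.toks.size(); ++t)
        if (b.toks[t] != EOS) body.push_back(b.toks[t]);
      toks[j] = IntegerVector(body.begin(), body.end());
      scores[j] = score(b);
    }
    out[i] = List::create(_["tokens"] = toks, _["scores"] = scores);
  }
  return out;
}
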