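// Sequence-network engine: forward, backpropagation-through-time and Adam
// training for the architectures the package declares (dense stacks, BiLSTM,
// GRU, dilated 1-D convolutions with residual blocks, layer normalization,
// multi-head self-attention). Data layout: arma::cube (channels, batch, time)
// so each time step is one contiguous (C x B) slice and every per-step
// operation is a GEMM over the whole batch.

#include <RcppArmadillo.h>
#include <memory>
#include <random>
#include <stdexcept>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::mt19937_64 Rng;

static mat glorot(int rows, int cols, Rng& rng) {
  double lim = std::sqrt(6.0 / (rows + cols));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat w(rows, cols);
  for (uword i = 0; i < w.n_elem; ++i) w(i) = u(rng);
  return w;
}

struct Param {
  mat value;
  mat grad;
  mat m, v;  // Adam state
  std::string name;
  Param(mat val, std::string nm) : value(std::move(val)), name(std::move(nm)) {
    grad = zeros<mat>(value.n_rows, value.n_cols);
    m = grad; v = grad;
  }
};

struct Layer {
  virtual ~Layer() {}
  virtual cube forward(const cube& x, bool training, Rng& rng) = 0;
  virtual cube backward(const cube& gy) = 0;
  virtual void collect(std::vector<Param*>& ps) {}
  virtual void release_cache() {}
};

static inline mat flat_view(const cube& x) {
  // (C, B, T) cube as a (C, B*T) matrix sharing memory
  return mat(const_cast<double*>(x.memptr()), x.n_rows, x.n_cols * x.n_slices, false, true);
}

// ---------------------------------------------------------------- dense ----
struct Dense : Layer {
  Param W, b;
  cube xin;
  bool cache;
  Dense(int in, int out, Rng& rng, const std::string& nm)
    : W(glorot(out, in, rng), nm + ".W"), b(zeros<mat>(out, 1), nm + ".b"), cache(false) {}
  cube forward(const cube& x, bool training, Rng&) override {
    cache = training;
    if (training) xin = x;
    cube y(W.value.n_rows, x.n_cols, x.n_slices);
    mat ym(y.memptr(), y.n_rows, y.n_cols * y.n_slices, false, true);
    ym = W.value * flat_view(x);
    ym.each_col() += b.value.col(0);
    return y;
  }
  cube backward(const cube& gy) override {
    mat gym = flat_view(gy);
    mat xm = flat_view(xin);
    W.grad += gym * xm.t();
    b.grad += sum(gym, 1);
    cube gx(xin.n_rows, xin.n_cols, xin.n_slices);
    mat gxm(gx.memptr(), gx.n_rows, gx.n_cols * gx.n_slices, false, true);
    gxm = W.value.t() * gym;
    return gx;
  }
  void collect(std::vector<Param*>& ps) override { ps.push_back(&W); ps.push_back(&b); }
  void release_cache() override { xin.reset(); }
};

// ----------------------------------------------------------- activations ---
struct Sigmoid : Layer {
  cube yout;
  cube forward(const cube& x, bool training, Rng&) override {
    yout = 1.0 / (1.0 + exp(-x));
    return yout;
  }
  cube backward(const cube& gy) override { return gy % yout % (1.0 - yout); }
  void release_cache() override { yout.reset(); }
};

struct Relu : Layer {
  cube yout;
  cube forward(const cube& x, bool training, Rng&) override {
    yout = clamp(x, 0.0, datum::inf);
    return yout;
  }
  cube backward(const cube& gy) override {
    cube g = gy;
    g.elem(find(yout == 0.0)).zeros();
    return g;
  }
  void release_cache() override { yout.reset(); }
};

struct Softmax : Layer {
  cube probs;
  cube forward(const cube& x, bool training, Rng&) override {
    probs = x;
    mat pm = flat_view(probs);
    pm.each_row() -= max(pm, 0);
    pm = exp(pm);
    pm.each_row() /= sum(pm, 0);
    return probs;
  }
  cube backward(const cube& gy) override {
    mat pm = flat_view(probs);
    mat gym = flat_view(gy);
    cube gx(probs.n_rows, probs.n_cols, probs.n_slices);
    mat gxm(gx.memptr(), gx.n_rows, gx.n_cols * gx.n_slices, false, true);
    rowvec dot = sum(gym % pm, 0);
    gxm = pm % (gym.each_row() - dot);
    return gx;
  }
  void release_cache() override { /* probs kept: they are the output */ }
};

// -------------------------------------------------------------- dropout ----
struct Dropout : Layer {
  double p;
  cube mask;
  bool active;
  explicit Dropout(double prob) : p(prob), active(false) {}
  cube forward(const cube& x, bool training, Rng& rng) override {
    active = training;
    if (!training) return x;
    std::bernoulli_distribution keep(1.0 - p);
    mask.set_size(x.n_rows, x.n_cols, x.n_slices);
    double s = 1.0 / (1.0 - p);
    for (uword i = 0; i < mask.n_elem; ++i) mask(i) = keep(rng) ? s : 0.0;
    return x % mask;
  }
  cube backward(const cube& gy) override { return active ? cube(gy % mask) : gy; }
  void release_cache() override { mask.reset(); }
};

struct SpatialDropout : Layer {
  double p;
  mat mask;  // (C, B), shared across time
  bool active;
  explicit SpatialDropout(double prob) : p(prob), active(false) {}
  cube forward(const cube& x, bool training, Rng& rng) override {
    active = training;
    if (!training) return x;
    std::bernoulli_distribution keep(1.0 - p);
    mask.set_size(x.n_rows, x.n_cols);
    double s = 1.0 / (1.0 - p);
    for (uword i = 0; i < mask.n_elem; ++i) mask(i) = keep(rng) ? s : 0.0;
    cube y = x;
    for (uword t = 0; t < y.n_slices; ++t) y.slice(t) %= mask;
    return y;
  }
  cube backward(const cube& gy) override {
    if (!active) return gy;
    cube g = gy;
    for (uword t = 0; t < g.n_slices; ++t) g.slice(t) %= mask;
    return g;
  }
  void release_cache() override { mask.reset(); }
};

// ------------------------------------------------------------ layer norm ---
struct LayerNorm : Layer {
  Param gamma, beta;
  cube xhat;
  rowvec inv_sig;
  static constexpr double eps = 1e-5;
  LayerNorm(int ch, const std::string& nm)
    : gamma(ones<mat>(ch, 1), nm + ".gamma"), beta(zeros<mat>(ch, 1), nm + ".beta") {}
  cube forward(const cube& x, bool training, Rng&) override {
    xhat = x;
    mat xm = flat_view(xhat);
    rowvec mu = mean(xm, 0);
    xm.each_row() -= mu;
    rowvec var = mean(xm % xm, 0);
    inv_sig = 1.0 / sqrt(var + eps);
    xm.each_row() %= inv_sig;
    cube y = xhat;
    mat ym = flat_view(y);
    ym.each_col() %= gamma.value.col(0);
    ym.each_col() += beta.value.col(0);
    return y;
  }
  cube backward(const cube& gy) override {
    mat gym = flat_view(gy);
    mat xh = flat_view(xhat);
    gamma.grad += sum(gym % xh, 1);
    beta.grad += sum(gym, 1);
    mat dxh = gym.each_col() % gamma.value.col(0);
    rowvec m1 = mean(dxh, 0);
    rowvec m2 = mean(dxh % xh, 0);
    cube gx(gy.n_rows, gy.n_cols, gy.n_slices);
    mat gxm(gx.memptr(), gx.n_rows, gx.n_cols * gx.n_slices, false, true);
    gxm = dxh.each_row() - m1;
    gxm -= xh.each_row() % m2;
    gxm.each_row() %= inv_sig;
    return gx;
  }
  void collect(std::vector<Param*>& ps) override { ps.push_back(&gamma); ps.push_back(&beta); }
  void release_cache() override { xhat.reset(); inv_sig.reset(); }
};

// --------------------------------------------------------------- conv1d ----
struct Conv1d : Layer {
  std::vector<Param> Wt;  // one (out x in) matrix per kernel tap
  Param b;
  int k, dilation, center;
  cube xin;
  Conv1d(int in, int out, int kk, int dil, Rng& rng, const std::string& nm)
    : b(zeros<mat>(out, 1), nm + ".b"), k(kk), dilation(dil), center((kk - 1) / 2) {
    // taps share one Glorot fan (k*in -> out)
    double lim = std::sqrt(6.0 / (k * in + out));
    std::uniform_real_distribution<double> u(-lim, lim);
    for (int j = 0; j < k; ++j) {
      mat w(out, in);
      for (uword i = 0; i < w.n_elem; ++i) w(i) = u(rng);
      Wt.emplace_back(std::move(w), nm + ".W" + std::to_string(j));
    }
  }
  cube forward(const cube& x, bool training, Rng&) override {
    xin = x;
    int T = x.n_slices;
    cube y(Wt[0].value.n_rows, x.n_cols, T, fill::zeros);
    for (int j = 0; j < k; ++j) {
      int o = (j - center) * dilation;
      int t0 = std::max(0, -o), t1 = std::min(T, T - o);
      for (int t = t0; t < t1; ++t) y.slice(t) += Wt[j].value * x.slice(t + o);
    }
    for (int t = 0; t < T; ++t) y.slice(t).each_col() += b.value.col(0);
    return y;
  }
  cube backward(const cube& gy) override {
    int T = gy.n_slices;
    cube gx(xin.n_rows, xin.n_cols, T, fill::zeros);
    for (int j = 0; j < k; ++j) {
      int o = (j - center) * dilation;
      int t0 = std::max(0, -o), t1 = std::min(T, T - o);
      for (int t = t0; t < t1; ++t) {
        gx.slice(t + o) += Wt[j].value.t() * gy.slice(t);
        Wt[j].grad += gy.slice(t) * xin.slice(t + o).t();
      }
    }
    for (int t = 0; t < T; ++t) b.grad += sum(gy.slice(t), 1);
    return gx;
  }
  void collect(std::vector<Param*>& ps) override {
    for (auto& w : Wt) ps.push_back(&w);
    ps.push_back(&b);
  }
  void release_cache() override { xin.reset(); }
};

// ----------------------------------------------------------------- lstm ----
// one direction; gate order (i, f, g, o), single bias vector (4h)
struct LstmDir {
  Param W, R, b;
  int h;
  bool rev;
  cube Gt;      // activated gates (4h, B, T)
  cube Ct;      // cell states
  cube Ht;      // hidden states
  cube TanhC;   // tanh(cell)
  const cube* xin;
  LstmDir(int in, int hh, bool reverse, Rng& rng, const std::string& nm)
    : W(glorot(4 * hh, in, rng), nm + ".W"),
      R(glorot(4 * hh, hh, rng), nm + ".R"),
      b(zeros<mat>(4 * hh, 1), nm + ".b"), h(hh), rev(reverse) {
    // forget-gate bias 1 stabilises early training
    b.value.rows(h, 2 * h - 1).ones();
  }
  inline int step(int i, int T) const { return rev ? T - 1 - i : i; }
  cube forward(const cube& x, bool keep_cache) {
    int T = x.n_slices, B = x.n_cols;
    xin = &x;
    cube Zx(4 * h, B, T);
    {
      mat zm(Zx.memptr(), 4 * h, (size_t)B * T, false, true);
      zm = W.value * flat_view(x);
      zm.each_col() += b.value.col(0);
    }
    Ht.set_size(h, B, T);
    if (keep_cache) { Gt.set_size(4 * h, B, T); Ct.set_size(h, B, T); TanhC.set_size(h, B, T); }
    mat hprev(h, B, fill::zeros), cprev(h, B, fill::zeros);
    for (int s = 0; s < T; ++s) {
      int t = step(s, T);
      mat z = Zx.slice(t) + R.value * hprev;
      mat ig = 1.0 / (1.0 + exp(-z.rows(0, h - 1)));
      mat fg = 1.0 / (1.0 + exp(-z.rows(h, 2 * h - 1)));
      mat gg = tanh(z.rows(2 * h, 3 * h - 1));
      mat og = 1.0 / (1.0 + exp(-z.rows(3 * h, 4 * h - 1)));
      mat c = fg % cprev + ig % gg;
      mat tc = tanh(c);
      mat hh = og % tc;
      if (keep_cache) {
        Gt.slice(t).rows(0, h - 1) = ig;
        Gt.slice(t).rows(h, 2 * h - 1) = fg;
        Gt.slice(t).rows(2 * h, 3 * h - 1) = gg;
        Gt.slice(t).rows(3 * h, 4 * h - 1) = og;
        Ct.slice(t) = c;
        TanhC.slice(t) = tc;
      }
      Ht.slice(t) = hh;
      hprev = hh; cprev = c;
    }
    return Ht;
  }
  cube backward(const cube& gy) {
    int T = gy.n_slices, B = gy.n_cols;
    cube gx(xin->n_rows, B, T, fill::zeros);
    mat dh_next(h, B, fill::zeros), dc_next(h, B, fill::zeros);
    mat zerosm(h, B, fill::zeros);
    for (int s = T - 1; s >= 0; --s) {
      int t = step(s, T);
      int tprev = s > 0 ? step(s - 1, T) : -1;
      mat ig = Gt.slice(t).rows(0, h - 1);
      mat fg = Gt.slice(t).rows(h, 2 * h - 1);
      mat gg = Gt.slice(t).rows(2 * h, 3 * h - 1);
      mat og = Gt.slice(t).rows(3 * h, 4 * h - 1);
      const mat& tc = TanhC.slice(t);
      mat dh = gy.slice(t) + dh_next;
      mat dc = dc_next + dh % og % (1.0 - tc % tc);
      mat cprev = tprev >= 0 ? mat(Ct.slice(tprev)) : zerosm;
      mat hprev = tprev >= 0 ? mat(Ht.slice(tprev)) : zerosm;
      mat dz(4 * h, B);
      dz.rows(0, h - 1) = (dc % gg) % ig % (1.0 - ig);
      dz.rows(h, 2 * h - 1) = (dc % cprev) % fg % (1.0 - fg);
      dz.rows(2 * h, 3 * h - 1) = (dc % ig) % (1.0 - gg % gg);
      dz.rows(3 * h, 4 * h - 1) = (dh % tc) % og % (1.0 - og);
      W.grad += dz * xin->slice(t).t();
      R.grad += dz * hprev.t();
      b.grad += sum(dz, 1);
      gx.slice(t) = W.value.t() * dz;
      dh_next = R.value.t() * dz;
      dc_next = dc % fg;
    }
    return gx;
  }
  void release() { Gt.reset(); Ct.reset(); Ht.reset(); TanhC.reset(); }
};

struct BiLstm : Layer {
  LstmDir fwd, bwd;
  int h;
  cube xkeep;
  BiLstm(int in, int hh, Rng& rng, const std::string& nm)
    : fwd(in, hh, false, rng, nm + ".fwd"), bwd(in, hh, true, rng, nm + ".bwd"), h(hh) {}
  cube forward(const cube& x, bool training, Rng&) override {
    xkeep = x;  // LstmDir holds a pointer into this copy
    cube hf = fwd.forward(xkeep, training);
    cube hb = bwd.forward(xkeep, training);
    cube y(2 * h, x.n_cols, x.n_slices);
    for (uword t = 0; t < x.n_slices; ++t) {
      y.slice(t).rows(0, h - 1) = hf.slice(t);
      y.slice(t).rows(h, 2 * h - 1) = hb.slice(t);
    }
    return y;
  }
  cube backward(const cube& gy) override {
    cube gf(h, gy.n_cols, gy.n_slices), gb(h, gy.n_cols, gy.n_slices);
    for (uword t = 0; t < gy.n_slices; ++t) {
      gf.slice(t) = gy.slice(t).rows(0, h - 1);
      gb.slice(t) = gy.slice(t).rows(h, 2 * h - 1);
    }
    cube gx = fwd.backward(gf);
    gx += bwd.backward(gb);
    return gx;
  }
  void collect(std::vector<Param*>& ps) override {
    ps.push_back(&fwd.W); ps.push_back(&fwd.R); ps.push_back(&fwd.b);
    ps.push_back(&bwd.W); ps.push_back(&bwd.R); ps.push_back(&bwd.b);
  }
  void release_cache() override { fwd.release(); bwd.release(); xkeep.reset(); }
};

// ------------------------------------------------------------------ gru ----
// single direction; gate order (r, z, n); bias on the input projection only
struct Gru : Layer {
  Param W, R, b;
  int h;
  cube Rt, Zt, Nt, Zhn, Ht;
  cube xkeep;
  Gru(int in, int hh, Rng& rng, const std::string& nm)
    : W(glorot(3 * hh, in, rng), nm + ".W"),
      R(glorot(3 * hh, hh, rng), nm + ".R"),
      b(zeros<mat>(3 * hh, 1), nm + ".b"), h(hh) {}
  cube forward(const cube& x, bool training, Rng&) override {
    int T = x.n_slices, B = x.n_cols;
    xkeep = x;
    cube Zx(3 * h, B, T);
    {
      mat zm(Zx.memptr(), 3 * h, (size_t)B * T, false, true);
      zm = W.value * flat_view(xkeep);
      zm.each_col() += b.value.col(0);
    }
    Ht.set_size(h, B, T);
    if (training) {
      Rt.set_size(h, B, T); Zt.set_size(h, B, T);
      Nt.set_size(h, B, T); Zhn.set_size(h, B, T);
    }
    mat hprev(h, B, fill::zeros);
    for (int t = 0; t < T; ++t) {
      mat zh = R.value * hprev;
      mat r = 1.0 / (1.0 + exp(-(Zx.slice(t).rows(0, h - 1) + zh.rows(0, h - 1))));
      mat z = 1.0 / (1.0 + exp(-(Zx.slice(t).rows(h, 2 * h - 1) + zh.rows(h, 2 * h - 1))));
      mat zhn = zh.rows(2 * h, 3 * h - 1);
      mat n = tanh(Zx.slice(t).rows(2 * h, 3 * h - 1) + r % zhn);
      mat hh = (1.0 - z) % n + z % hprev;
      if (Rt.n_elem) {
        Rt.slice(t) = r; Zt.slice(t) = z; Nt.slice(t) = n; Zhn.slice(t) = zhn;
      }
      Ht.slice(t) = hh;
      hprev = hh;
    }
    return Ht;
  }
  cube backward(const cube& gy) override {
    int T = gy.n_slices, B = gy.n_cols;
    cube gx(xkeep.n_rows, B, T, fill::zeros);
    mat dh_next(h, B, fill::zeros);
    mat zerosm(h, B, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat hprev = t > 0 ? mat(Ht.slice(t - 1)) : zerosm;
      const mat& r = Rt.slice(t);
      const mat& z = Zt.slice(t);
      const mat& n = Nt.slice(t);
      const mat& zhn = Zhn.slice(t);
      mat dh = gy.slice(t) + dh_next;
      mat dz = dh % (hprev - n);
      mat dn = dh % (1.0 - z);
      mat dh_prev = dh % z;
      mat dzn = dn % (1.0 - n % n);
      mat dzr = (dzn % zhn) % r % (1.0 - r);
      mat dzz = dz % z % (1.0 - z);
      mat dZx(3 * h, B), dZh(3 * h, B);
      dZx.rows(0, h - 1) = dzr;
      dZx.rows(h, 2 * h - 1) = dzz;
      dZx.rows(2 * h, 3 * h - 1) = dzn;
      dZh.rows(0, h - 1) = dzr;
      dZh.rows(h, 2 * h - 1) = dzz;
      dZh.rows(2 * h, 3 * h - 1) = dzn % r;
      W.grad += dZx * xkeep.slice(t).t();
      R.grad += dZh * hprev.t();
      b.grad += sum(dZx, 1);
      gx.slice(t) = W.value.t() * dZx;
      dh_next = dh_prev + R.value.t() * dZh;
    }
    return gx;
  }
  void collect(std::vector<Param*>& ps) override {
    ps.push_back(&W); ps.push_back(&R); ps.push_back(&b);
  }
  void release_cache() override { Rt.reset(); Zt.reset(); Nt.reset(); Zhn.reset(); Ht.reset(); xkeep.reset(); }
};

// ------------------------------------------------------- self-attention ----
// forward-only: scaled dot-product attention with H heads over D total
// query/key/value channels, output projected back to the input width
struct SelfAttention : Layer {
  Param Wq, Wk, Wv, bq, bk, bv, Wo, bo;
  int heads, D, dh;
  SelfAttention(int in, int hh, int DD, Rng& rng, const std::string& nm)
    : Wq(glorot(DD, in, rng), nm + ".Wq"), Wk(glorot(DD, in, rng), nm + ".Wk"),
      Wv(glorot(DD, in, rng), nm + ".Wv"),
      bq(zeros<mat>(DD, 1), nm + ".bq"), bk(zeros<mat>(DD, 1), nm + ".bk"),
      bv(zeros<mat>(DD, 1), nm + ".bv"),
      Wo(glorot(in, DD, rng), nm + ".Wo"), bo(zeros<mat>(in, 1), nm + ".bo"),
      heads(hh), D(DD), dh(DD / hh) {}
  cube forward(const cube& x, bool training, Rng&) override {
    int C = x.n_rows, B = x.n_cols, T = x.n_slices;
    cube y(C, B, T);
    double scale = 1.0 / std::sqrt((double)dh);
    mat Xb(C, T);
    for (int bi = 0; bi < B; ++bi) {
      for (int t = 0; t < T; ++t) Xb.col(t) = x.slice(t).col(bi);
      mat Q = Wq.value * Xb; Q.each_col() += bq.value.col(0);
      mat K = Wk.value * Xb; K.each_col() += bk.value.col(0);
      mat V = Wv.value * Xb; V.each_col() += bv.value.col(0);
      mat Conc(D, T);
      for (int hh2 = 0; hh2 < heads; ++hh2) {
        int r0 = hh2 * dh, r1 = r0 + dh - 1;
        mat S = K.rows(r0, r1).t() * Q.rows(r0, r1) * scale;  // (T keys x T queries)
        S.each_row() -= max(S, 0);
        S = exp(S);
        S.each_row() /= sum(S, 0);
        Conc.rows(r0, r1) = V.rows(r0, r1) * S;
      }
      mat Yb = Wo.value * Conc;
      Yb.each_col() += bo.value.col(0);
      for (int t = 0; t < T; ++t) y.slice(t).col(bi) = Yb.col(t);
    }
    return y;
  }
  cube backward(const cube&) override {
    throw std::runtime_error("training through self_attention layers is not supported");
  }
  void collect(std::vector<Param*>& ps) override {
    ps.push_back(&Wq); ps.push_back(&bq);
    ps.push_back(&Wk); ps.push_back(&bk);
    ps.push_back(&Wv); ps.push_back(&bv);
    ps.push_back(&Wo); ps.push_back(&bo);
  }
};

// -------------------------------------------------------- residual block ---
struct ResBlock : Layer {
  std::vector<std::unique_ptr<Layer>> inner;
  std::unique_ptr<Dense> skip;  // kernel-1 projection when channels change
  cube xkeep;
  cube forward(const cube& x, bool training, Rng& rng) override {
    xkeep = x;
    cube h = x;
    for (auto& ly : inner) h = ly->forward(h, training, rng);
    if (skip) h += skip->forward(x, training, rng);
    else h += x;
    return h;
  }
  cube backward(const cube& gy) override {
    cube g = gy;
    for (auto it = inner.rbegin(); it != inner.rend(); ++it) g = (*it)->backward(g);
    if (skip) g += skip->backward(gy);
    else g += gy;
    return g;
  }
  void collect(std::vector<Param*>& ps) override {
    for (auto& ly : inner) ly->collect(ps);
    if (skip) skip->collect(ps);
  }
  void release_cache() override {
    for (auto& ly : inner) ly->release_cache();
    if (skip) skip->release_cache();
    xkeep.reset();
  }
};

// -------------------------------------------------------------- network ----
struct Network {
  std::vector<std::unique_ptr<Layer>> layers;
  Rng rng;

  std::vector<Param*> params() {
    std::vector<Param*> ps;
    for (auto& ly : layers) ly->collect(ps);
    return ps;
  }
  cube forward(const cube& x, bool training) {
    cube h = x;
    for (auto& ly : layers) h = ly->forward(h, training, rng);
    return h;
  }
  cube backward(const cube& gtop) {
    cube g = gtop;
    for (auto it = layers.rbegin(); it != layers.rend(); ++it) g = (*it)->backward(g);
    return g;
  }
  void zero_grads() {
    for (Param* p : params()) p->grad.zeros();
  }
  void release() {
    for (auto& ly : layers) ly->release_cache();
  }
};

static std::unique_ptr<Layer> build_layer(const Rcpp::List& ls, Rng& rng, int idx);

static void build_into(std::vector<std::unique_ptr<Layer>>& out,
                       const Rcpp::List& spec, Rng& rng, int base) {
  for (int i = 0; i < spec.size(); ++i) {
    Rcpp::List ls = spec[i];
    out.push_back(build_layer(ls, rng, base + i));
  }
}

static std::unique_ptr<Layer> build_layer(const Rcpp::List& ls, Rng& rng, int idx) {
  std::string kind = Rcpp::as<std::string>(ls["kind"]);
  std::string nm = "L" + std::to_string(idx) + "." + kind;
  int in = ls.containsElementNamed("in") ? Rcpp::as<int>(ls["in"]) : 0;
  if (kind == "dense")
    return std::make_unique<Dense>(in, Rcpp::as<int>(ls["units"]), rng, nm);
  if (kind == "sigmoid") return std::make_unique<Sigmoid>();
  if (kind == "relu") return std::make_unique<Relu>();
  if (kind == "softmax") return std::make_unique<Softmax>();
  if (kind == "dropout") return std::make_unique<Dropout>(Rcpp::as<double>(ls["p"]));
  if (kind == "spatial_dropout")
    return std::make_unique<SpatialDropout>(Rcpp::as<double>(ls["p"]));
  if (kind == "layer_norm") return std::make_unique<LayerNorm>(in, nm);
  if (kind == "bilstm")
    return std::make_unique<BiLstm>(in, Rcpp::as<int>(ls["units"]), rng, nm);
  if (kind == "gru")
    return std::make_unique<Gru>(in, Rcpp::as<int>(ls["units"]), rng, nm);
  if (kind == "conv1d")
    return std::make_unique<Conv1d>(in, Rcpp::as<int>(ls["filters"]),
                                    Rcpp::as<int>(ls["kernel"]),
                                    Rcpp::as<int>(ls["dilation"]), rng, nm);
  if (kind == "self_attention")
    return std::make_unique<SelfAttention>(in, Rcpp::as<int>(ls["heads"]),
                                           Rcpp::as<int>(ls["qkv_channels"]), rng, nm);
  if (kind == "resblock") {
    auto rb = std::make_unique<ResBlock>();
    Rcpp::List innerSpec = ls["layers"];
    build_into(rb->inner, innerSpec, rng, idx * 100);
    if (Rcpp::as<bool>(ls["skip_conv"])) {
      rb->skip = std::make_unique<Dense>(in, Rcpp::as<int>(ls["out"]), rng,
                                         nm + ".skip");
    }
    return rb;
  }
  throw std::runtime_error("unknown layer kind in engine spec: " + kind);
}

static cube as_cube(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  if (d.size() != 3) throw std::runtime_error("expected a 3-d array (channels, batch, time)");
  cube x(a.begin(), d[0], d[1], d[2]);
  return x;
}

static Rcpp::NumericVector wrap_cube(const cube& x) {
  Rcpp::NumericVector out(x.begin(), x.end());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export]]
SEXP nn_build(Rcpp::List spec, int seed) {
  auto* net = new Network();
  net->rng.seed((uint64_t)seed);
  build_into(net->layers, spec, net->rng, 0);
  Rcpp::XPtr<Network> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_nparams(SEXP netp) {
  Rcpp::XPtr<Network> net(netp);
  double total = 0;
  for (Param* p : net->params()) total += p->value.n_elem;
  return total;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_forward(SEXP netp, Rcpp::NumericVector x, bool training = false) {
  Rcpp::XPtr<Network> net(netp);
  cube out = net->forward(as_cube(x), training);
  net->release();
  return wrap_cube(out);
}

static double ce_loss(const cube& p, const cube& y) {
  double n = (double)p.n_cols * p.n_slices;
  return -accu(y % log(p + 1e-12)) / n;
}

// [[Rcpp::export]]
double nn_loss(SEXP netp, Rcpp::NumericVector x, Rcpp::NumericVector y) {
  Rcpp::XPtr<Network> net(netp);
  cube p = net->forward(as_cube(x), false);
  net->release();
  return ce_loss(p, as_cube(y));
}

// [[Rcpp::export]]
Rcpp::List nn_gradients(SEXP netp, Rcpp::NumericVector x, Rcpp::NumericVector y) {
  Rcpp::XPtr<Network> net(netp);
  net->zero_grads();
  cube yc = as_cube(y);
  cube p = net->forward(as_cube(x), true);
  double n = (double)p.n_cols * p.n_slices;
  cube gtop = -(yc / (p + 1e-12)) / n;
  net->backward(gtop);
  auto ps = net->params();
  Rcpp::List out(ps.size());
  Rcpp::CharacterVector nms(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    out[i] = Rcpp::wrap(ps[i]->grad);
    nms[i] = ps[i]->name;
  }
  out.attr("names") = nms;
  net->release();
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_get_params(SEXP netp) {
  Rcpp::XPtr<Network> net(netp);
  auto ps = net->params();
  Rcpp::List out(ps.size());
  Rcpp::CharacterVector nms(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    out[i] = Rcpp::wrap(ps[i]->value);
    nms[i] = ps[i]->name;
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export]]
void nn_set_params(SEXP netp, Rcpp::List values) {
  Rcpp::XPtr<Network> net(netp);
  auto ps = net->params();
  if ((size_t)values.size() != ps.size())
    throw std::runtime_error("parameter list length mismatch");
  for (size_t i = 0; i < ps.size(); ++i) {
    mat v = Rcpp::as<mat>(values[i]);
    if (v.n_rows != ps[i]->value.n_rows || v.n_cols != ps[i]->value.n_cols)
      throw std::runtime_error("parameter shape mismatch at " + ps[i]->name);
    ps[i]->value = v;
  }
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void step(std::vector<Param*>& ps) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (Param* p : ps) {
      p->m = b1 * p->m + (1.0 - b1) * p->grad;
      p->v = b2 * p->v + (1.0 - b2) * (p->grad % p->grad);
      p->value -= lr * (p->m / c1) / (sqrt(p->v / c2) + eps);
    }
  }
};

static cube gather(const cube& x, const uvec& idx) {
  cube out(x.n_rows, idx.n_elem, x.n_slices);
  for (uword t = 0; t < x.n_slices; ++t) out.slice(t) = x.slice(t).cols(idx);
  return out;
}

// evaluation-mode loss and frame accuracy, batched to bound memory
static void eval_set(Network& net, const cube& x, const cube& y, int batch,
                     double& loss, double& acc) {
  uword N = x.n_cols;
  double lsum = 0, correct = 0, frames = 0;
  for (uword at = 0; at < N; at += batch) {
    uword hi = std::min(N, at + (uword)batch);
    uvec idx = regspace<uvec>(at, hi - 1);
    cube xb = gather(x, idx), yb = gather(y, idx);
    cube p = net.forward(xb, false);
    net.release();
    lsum += ce_loss(p, yb) * (double)(hi - at);
    for (uword t = 0; t < p.n_slices; ++t) {
      for (uword b = 0; b < p.n_cols; ++b) {
        uword pa; p.slice(t).col(b).max(pa);
        uword ya; yb.slice(t).col(b).max(ya);
        if (pa == ya) correct += 1;
        frames += 1;
      }
    }
  }
  loss = lsum / (double)N;
  acc = 100.0 * correct / frames;
}

// [[Rcpp::export]]
Rcpp::List nn_train(SEXP netp, Rcpp::NumericVector x, Rcpp::NumericVector y,
                    Rcpp::NumericVector xval, Rcpp::NumericVector yval,
                    Rcpp::List opts, int seed) {
  Rcpp::XPtr<Network> net(netp);
  cube X = as_cube(x), Y = as_cube(y), Xv = as_cube(xval), Yv = as_cube(yval);
  int max_epochs = Rcpp::as<int>(opts["max_epochs"]);
  double lr0 = Rcpp::as<double>(opts["initial_lr"]);
  double drop = Rcpp::as<double>(opts["lr_drop"]);
  int period = Rcpp::as<int>(opts["lr_period"]);
  int batch = Rcpp::as<int>(opts["batch_size"]);
  int patience = Rcpp::as<int>(opts["patience"]);

  Rng shuffler((uint64_t)seed);
  Adam adam;
  auto ps = net->params();

  std::vector<double> h_train, h_val, h_acc, h_lr;
  double best_val = datum::inf, val_loss = 0, val_acc = 0;
  int wait = 0, best_epoch = 0;
  bool stopped = false;
  std::vector<mat> best_params;
  for (Param* p : ps) best_params.push_back(p->value);

  uword N = X.n_cols;
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    adam.lr = lr0 * std::pow(drop, epoch / period);
    std::shuffle(order.begin(), order.end(), shuffler);
    double tr_loss = 0;
    int nb = 0;
    for (uword at = 0; at < N; at += batch) {
      uword hi = std::min(N, at + (uword)batch);
      uvec idx(hi - at);
      for (uword i = at; i < hi; ++i) idx(i - at) = order[i];
      cube xb = gather(X, idx), yb = gather(Y, idx);
      net->zero_grads();
      cube p = net->forward(xb, true);
      double l = ce_loss(p, yb);
      if (!std::isfinite(l)) {
        net->release();
        throw Rcpp::exception("training diverged (non-finite loss)");
      }
      double n = (double)p.n_cols * p.n_slices;
      cube gtop = -(yb / (p + 1e-12)) / n;
      net->backward(gtop);
      net->release();
      adam.step(ps);
      tr_loss += l;
      ++nb;
      Rcpp::checkUserInterrupt();
    }
    eval_set(*net, Xv, Yv, batch, val_loss, val_acc);
    h_train.push_back(tr_loss / nb);
    h_val.push_back(val_loss);
    h_acc.push_back(val_acc);
    h_lr.push_back(adam.lr);
    if (val_loss < best_val - 1e-9) {
      best_val = val_loss;
      best_epoch = epoch + 1;
      wait = 0;
      for (size_t i = 0; i < ps.size(); ++i) best_params[i] = ps[i]->value;
    } else if (++wait >= patience) {
      stopped = true;
      break;
    }
  }
  for (size_t i = 0; i < ps.size(); ++i) ps[i]->value = best_params[i];
  return Rcpp::List::create(
    Rcpp::Named("train_loss") = h_train,
    Rcpp::Named("val_loss") = h_val,
    Rcpp::Named("val_acc") = h_acc,
    Rcpp::Named("lr") = h_lr,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("stopped_early") = stopped);
}
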