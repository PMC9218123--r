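// Two-level nested U-shaped density-map network with an optional
// self-normalization (beta) bypass head, implemented from first principles:
// im2col convolutions, max pooling, bilinear upsampling, spatial dropout,
// deep-supervised BCE loss, and Adam — all on CPU via Armadillo.
//
// Layout conventions: feature maps are arma::cube (H, W, C); a cube slice is
// one channel. Convolution weights are stored as (Cin*k*k, Cout) matrices so
// the forward pass is a single (H*W, Cin*k*k) x (Cin*k*k, Cout) product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------- parameters

struct Param {
  mat W; vec b;
  mat gW; vec gb;        // accumulated gradients
  mat mW, vW; vec mb, vb; // Adam state
  double lr_scale = 1.0; // per-module learning-rate multiplier
  bool has_bias = true;

  void init_state() {
    gW.zeros(W.n_rows, W.n_cols); mW.zeros(W.n_rows, W.n_cols);
    vW.zeros(W.n_rows, W.n_cols);
    gb.zeros(b.n_elem); mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
};

// ------------------------------------------------------------- conv 3x3 pad1

static void im2col3(const cube& in, mat& cols) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  cols.set_size(H * W, C * 9);
  for (int c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int j = c * 9 + (dj + 1) * 3 + (di + 1);
        double* dst = cols.colptr(j);
        std::memset(dst, 0, sizeof(double) * H * W);
        const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
        const int len = r1 - r0 + 1;
        if (len <= 0) continue;
        for (int jc = 0; jc < W; ++jc) {
          const int js = jc + dj;
          if (js < 0 || js >= W) continue;
          std::memcpy(dst + jc * H + r0, sl.colptr(js) + r0 + di,
                      sizeof(double) * len);
        }
      }
    }
  }
}

static cube conv3_fwd(const cube& in, const Param& p) {
  const int H = in.n_rows, W = in.n_cols;
  const int Cout = p.W.n_cols;
  mat cols;
  im2col3(in, cols);
  cube out(H, W, Cout);
  mat outM(out.memptr(), H * W, Cout, false, true);
  outM = cols * p.W;
  outM.each_row() += p.b.t();
  return out;
}

// dOut -> dIn; accumulates parameter gradients into p.gW / p.gb.
static cube conv3_bwd(const cube& in, Param& p, const cube& dOut) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat cols;
  im2col3(in, cols);
  const mat dOutM(const_cast<double*>(dOut.memptr()), H * W, dOut.n_slices,
                  false, true);
  p.gW += cols.t() * dOutM;
  p.gb += sum(dOutM, 0).t();
  mat dCols = dOutM * p.W.t();
  cube dIn(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dsl = dIn.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int j = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* src = dCols.colptr(j);
        const int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
        const int len = r1 - r0 + 1;
        if (len <= 0) continue;
        for (int jc = 0; jc < W; ++jc) {
          const int js = jc + dj;
          if (js < 0 || js >= W) continue;
          double* dp = dsl.colptr(js) + r0 + di;
          const double* sp = src + jc * H + r0;
          for (int r = 0; r < len; ++r) dp[r] += sp[r];
        }
      }
    }
  }
  return dIn;
}

// ------------------------------------------------------------------ conv 1x1

static cube conv1_fwd(const cube& in, const Param& p) {
  const int H = in.n_rows, W = in.n_cols;
  const mat inM(const_cast<double*>(in.memptr()), H * W, in.n_slices, false,
                true);
  cube out(H, W, p.W.n_cols);
  mat outM(out.memptr(), H * W, p.W.n_cols, false, true);
  outM = inM * p.W;
  outM.each_row() += p.b.t();
  return out;
}

static cube conv1_bwd(const cube& in, Param& p, const cube& dOut) {
  const int H = in.n_rows, W = in.n_cols;
  const mat inM(const_cast<double*>(in.memptr()), H * W, in.n_slices, false,
                true);
  const mat dOutM(const_cast<double*>(dOut.memptr()), H * W, dOut.n_slices,
                  false, true);
  p.gW += inM.t() * dOutM;
  p.gb += sum(dOutM, 0).t();
  cube dIn(H, W, in.n_slices);
  mat dInM(dIn.memptr(), H * W, in.n_slices, false, true);
  dInM = dOutM * p.W.t();
  return dIn;
}

// ---------------------------------------------------------------------- relu

static void relu_(cube& x) { x.transform([](double v) { return v > 0 ? v : 0.0; }); }

// act is the *activated* output; masks dGrad in place.
static void relu_bwd_(const cube& act, cube& dGrad) {
  dGrad %= conv_to<cube>::from(act > 0);
}

// ---------------------------------------------------------------- maxpool 2x2

static cube maxpool2_fwd(const cube& in, umat& argmax) {
  const int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  argmax.set_size(H * W, C);
  for (int c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    mat& o = out.slice(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int r = 2 * i, cc = 2 * j;
        double best = sl(r, cc); uword bi = r + cc * in.n_rows;
        if (sl(r + 1, cc) > best) { best = sl(r + 1, cc); bi = r + 1 + cc * in.n_rows; }
        if (sl(r, cc + 1) > best) { best = sl(r, cc + 1); bi = r + (cc + 1) * in.n_rows; }
        if (sl(r + 1, cc + 1) > best) { best = sl(r + 1, cc + 1); bi = r + 1 + (cc + 1) * in.n_rows; }
        o(i, j) = best;
        argmax(i + j * H, c) = bi;
      }
    }
  }
  return out;
}

static cube maxpool2_bwd(const cube& dOut, const umat& argmax, int Hin, int Win) {
  const int C = dOut.n_slices;
  cube dIn(Hin, Win, C, fill::zeros);
  const int n = dOut.n_rows * dOut.n_cols;
  for (int c = 0; c < C; ++c) {
    double* d = dIn.slice(c).memptr();
    const double* s = dOut.slice(c).memptr();
    const uword* a = argmax.colptr(c);
    for (int k = 0; k < n; ++k) d[a[k]] += s[k];
  }
  return dIn;
}

// ------------------------------------------------- bilinear 2x upsampling

// index/weight table for one axis: out index i maps to u = i/2 - 0.25.
static void up2_table(int n_out, int n_in, ivec& i0, ivec& i1, vec& w0, vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w0.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    const double u = (i + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(u);
    const double f = u - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > n_in - 1) hi = n_in - 1;
    i0[i] = lo; i1[i] = hi; w0[i] = 1.0 - f; w1[i] = f;
  }
}

static cube up2_fwd(const cube& in) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  ivec r0, r1, c0, c1; vec wr0, wr1, wc0, wc1;
  up2_table(2 * H, H, r0, r1, wr0, wr1);
  up2_table(2 * W, W, c0, c1, wc0, wc1);
  cube out(2 * H, 2 * W, C);
  mat tmp(2 * H, W);
  for (int c = 0; c < C; ++c) {
    const mat& sl = in.slice(c);
    for (int i = 0; i < 2 * H; ++i)
      tmp.row(i) = wr0[i] * sl.row(r0[i]) + wr1[i] * sl.row(r1[i]);
    mat& o = out.slice(c);
    for (int j = 0; j < 2 * W; ++j)
      o.col(j) = wc0[j] * tmp.col(c0[j]) + wc1[j] * tmp.col(c1[j]);
  }
  return out;
}

static cube up2_bwd(const cube& dOut, int Hin, int Win) {
  const int C = dOut.n_slices;
  ivec r0, r1, c0, c1; vec wr0, wr1, wc0, wc1;
  up2_table(2 * Hin, Hin, r0, r1, wr0, wr1);
  up2_table(2 * Win, Win, c0, c1, wc0, wc1);
  cube dIn(Hin, Win, C, fill::zeros);
  mat tmp(2 * Hin, Win);
  for (int c = 0; c < C; ++c) {
    tmp.zeros();
    const mat& dsl = dOut.slice(c);
    for (int j = 0; j < 2 * Win; ++j) {
      tmp.col(c0[j]) += wc0[j] * dsl.col(j);
      tmp.col(c1[j]) += wc1[j] * dsl.col(j);
    }
    mat& di = dIn.slice(c);
    for (int i = 0; i < 2 * Hin; ++i) {
      di.row(r0[i]) += wr0[i] * tmp.row(i);
      di.row(r1[i]) += wr1[i] * tmp.row(i);
    }
  }
  return dIn;
}

// upsample by repeated doubling to reach `target` (power-of-two ratio).
static cube up_to(const cube& in, int target) {
  cube out = in;
  while ((int)out.n_rows < target) out = up2_fwd(out);
  return out;
}

static cube down_from(const cube& dOut, int source) {
  cube d = dOut;
  while ((int)d.n_rows > source) d = up2_bwd(d, d.n_rows / 2, d.n_cols / 2);
  return d;
}

// ------------------------------------------------------------ spatial dropout

// Channelwise dropout; mask entries are 0 or 1/(1-p). Uses R's RNG.
static vec dropout_mask(int C, double p) {
  vec m(C);
  const double keep = 1.0 - p;
  for (int c = 0; c < C; ++c) m[c] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

static void apply_mask_(cube& x, const vec& m) {
  for (uword c = 0; c < x.n_slices; ++c) x.slice(c) *= m[c];
}

// ------------------------------------------------------------------ RSU block

// Residual U block: conv_in lifts to Cout, an inner encoder-decoder of depth d
// at Cmid channels refines it, and the result is added back to the lifted
// input (residual connection).
struct RSU {
  int d, Cin, Cmid, Cout;
  Param conv_in, convb;
  std::vector<Param> enc, dec; // enc[k-1] / dec[k-1] for inner level k = 1..d
};

struct RSUCache {
  cube x, h0;
  std::vector<cube> e;       // activated enc outputs, level 1..d (index 0..d-1)
  std::vector<cube> pin;     // pooled inputs to enc convs level 2..d (index k-2)
  std::vector<umat> pool_arg;
  cube pb; umat pb_arg;      // pooled input to bottom conv
  cube bt; vec bt_mask;
  std::vector<cube> cat_in;  // inputs to dec convs, stored for level k (index k-1)
  std::vector<cube> dec_out; // activated dec outputs, level k (index k-1)
  vec out_mask;
};

static cube rsu_fwd(const RSU& b, const cube& x, bool use_dropout, double rate,
                    RSUCache* cache) {
  cube h0 = conv3_fwd(x, b.conv_in); relu_(h0);
  std::vector<cube> e(b.d);
  std::vector<cube> pin(b.d > 1 ? b.d - 1 : 0);
  std::vector<umat> parg(b.d > 1 ? b.d - 1 : 0);
  e[0] = conv3_fwd(h0, b.enc[0]); relu_(e[0]);
  for (int k = 2; k <= b.d; ++k) {
    pin[k - 2] = maxpool2_fwd(e[k - 2], parg[k - 2]);
    e[k - 1] = conv3_fwd(pin[k - 2], b.enc[k - 1]); relu_(e[k - 1]);
  }
  umat pb_arg;
  cube pb = maxpool2_fwd(e[b.d - 1], pb_arg);
  cube bt = conv3_fwd(pb, b.convb); relu_(bt);
  vec bt_mask;
  if (use_dropout && rate > 0) { bt_mask = dropout_mask(bt.n_slices, rate); apply_mask_(bt, bt_mask); }

  std::vector<cube> cat_in(b.d), dec_out(b.d);
  cube u = bt;
  for (int k = b.d; k >= 1; --k) {
    cube uu = up2_fwd(u);
    cat_in[k - 1] = join_slices(uu, e[k - 1]);
    u = conv3_fwd(cat_in[k - 1], b.dec[k - 1]); relu_(u);
    dec_out[k - 1] = u;
  }
  vec out_mask;
  if (use_dropout && rate > 0) { out_mask = dropout_mask(u.n_slices, rate); apply_mask_(u, out_mask); }
  cube out = u + h0;
  if (cache) {
    cache->x = x; cache->h0 = h0; cache->e = std::move(e);
    cache->pin = std::move(pin); cache->pool_arg = std::move(parg);
    cache->pb = std::move(pb); cache->pb_arg = std::move(pb_arg);
    cache->bt = bt; cache->bt_mask = bt_mask;
    cache->cat_in = std::move(cat_in); cache->dec_out = std::move(dec_out);
    cache->out_mask = out_mask;
  }
  return out;
}

static cube rsu_bwd(RSU& b, const RSUCache& c, const cube& dOut) {
  cube dh0 = dOut;
  cube du = dOut;
  if (c.out_mask.n_elem) apply_mask_(du, c.out_mask);
  std::vector<cube> de(b.d);
  // decoder path backward (forward ran k = d..1, so reverse is k = 1..d)
  for (int k = 1; k <= b.d; ++k) {
    relu_bwd_(c.dec_out[k - 1], du);
    cube dCat = conv3_bwd(c.cat_in[k - 1], b.dec[k - 1], du);
    cube dUU = dCat.slices(0, b.Cmid - 1);
    cube dE = dCat.slices(b.Cmid, dCat.n_slices - 1);
    if (de[k - 1].n_elem) de[k - 1] += dE; else de[k - 1] = dE;
    du = up2_bwd(dUU, dUU.n_rows / 2, dUU.n_cols / 2);
  }
  // du is now the gradient at bt (post-dropout)
  if (c.bt_mask.n_elem) apply_mask_(du, c.bt_mask);
  relu_bwd_(c.bt, du);
  cube dPb = conv3_bwd(c.pb, b.convb, du);
  cube dEd = maxpool2_bwd(dPb, c.pb_arg, c.e[b.d - 1].n_rows, c.e[b.d - 1].n_cols);
  de[b.d - 1] += dEd;
  for (int k = b.d; k >= 2; --k) {
    cube dE = de[k - 1];
    relu_bwd_(c.e[k - 1], dE);
    cube dP = conv3_bwd(c.pin[k - 2], b.enc[k - 1], dE);
    de[k - 2] += maxpool2_bwd(dP, c.pool_arg[k - 2], c.e[k - 2].n_rows,
                              c.e[k - 2].n_cols);
  }
  cube dE1 = de[0];
  relu_bwd_(c.e[0], dE1);
  dh0 += conv3_bwd(c.h0, b.enc[0], dE1);
  relu_bwd_(c.h0, dh0);
  return conv3_bwd(c.x, b.conv_in, dh0);
}

// ----------------------------------------------------------------- network

struct NetConfig {
  int mode;               // 0 = dm, 1 = sndm
  int input_size;
  int n_stages;           // encoder stages incl. bottleneck
  int base_channels;
  int channel_cap;
  std::vector<int> depths; // length 2*n_stages - 1 (encoders then decoders)
  double dropout_rate;
  int beta_activation;    // 0 = scaled sigmoid, 1 = relu
  double lambda;
  int beta_hidden;
  double beta_lr_scale;
};

struct Net {
  NetConfig cfg;
  std::vector<int> ch, mid;
  std::vector<RSU> encB, decB;
  std::vector<Param> sideC; // 1x1 convs, one per side output
  Param fuseC;              // 1x1 fusion conv
  Param fc1, fc2;           // beta head
  long t_adam = 0;
  std::vector<Param*> params;

  int K() const { return cfg.n_stages; } // number of side outputs
};

static double rnorm_he(double fan_in) {
  return norm_rand() * std::sqrt(2.0 / fan_in);
}

static void init_conv(Param& p, int Cin, int Cout, int k, double bias0 = 0.0) {
  p.W.set_size(Cin * k * k, Cout);
  for (uword i = 0; i < p.W.n_elem; ++i) p.W[i] = rnorm_he(Cin * k * k);
  p.b.set_size(Cout); p.b.fill(bias0);
  p.init_state();
}

static void init_rsu(RSU& b, int Cin, int Cmid, int Cout, int d) {
  b.d = d; b.Cin = Cin; b.Cmid = Cmid; b.Cout = Cout;
  init_conv(b.conv_in, Cin, Cout, 3);
  b.enc.resize(d); b.dec.resize(d);
  init_conv(b.enc[0], Cout, Cmid, 3);
  for (int k = 2; k <= d; ++k) init_conv(b.enc[k - 1], Cmid, Cmid, 3);
  init_conv(b.convb, Cmid, Cmid, 3);
  for (int k = d; k >= 2; --k) init_conv(b.dec[k - 1], 2 * Cmid, Cmid, 3);
  init_conv(b.dec[0], 2 * Cmid, Cout, 3);
}

static void register_params(Net& n) {
  n.params.clear();
  auto add_rsu = [&](RSU& b) {
    n.params.push_back(&b.conv_in);
    for (auto& p : b.enc) n.params.push_back(&p);
    n.params.push_back(&b.convb);
    for (auto& p : b.dec) n.params.push_back(&p);
  };
  for (auto& b : n.encB) add_rsu(b);
  for (auto& b : n.decB) add_rsu(b);
  for (auto& p : n.sideC) n.params.push_back(&p);
  n.params.push_back(&n.fuseC);
  if (n.cfg.mode == 1) { n.params.push_back(&n.fc1); n.params.push_back(&n.fc2); }
}

static Net* build_net(const NetConfig& cfg) {
  Net* n = new Net();
  n->cfg = cfg;
  const int S = cfg.n_stages;
  n->ch.resize(S); n->mid.resize(S);
  for (int s = 0; s < S; ++s) {
    n->ch[s] = std::min(cfg.base_channels << s, cfg.channel_cap);
    n->mid[s] = std::max(2, n->ch[s] / 2);
  }
  // divisibility: stage s runs at N / 2^s and its inner U needs 2^depth more
  for (int s = 0; s < S; ++s) {
    int need = 1 << (s + cfg.depths[s]);
    if (cfg.input_size % need != 0)
      Rcpp::stop("input_size must be divisible by %d for this stage layout; resize the input or reduce n_stages/rsu_depths", need);
  }
  n->encB.resize(S);
  init_rsu(n->encB[0], 3, n->mid[0], n->ch[0], cfg.depths[0]);
  for (int s = 1; s < S; ++s)
    init_rsu(n->encB[s], n->ch[s - 1], n->mid[s], n->ch[s], cfg.depths[s]);
  n->decB.resize(S - 1);
  for (int s = S - 2; s >= 0; --s) {
    int prev = (s == S - 2) ? n->ch[S - 1] : n->ch[s + 1];
    init_rsu(n->decB[s], prev + n->ch[s], n->mid[s], n->ch[s],
             cfg.depths[S + (S - 2 - s)]);
  }
  n->sideC.resize(n->K());
  for (int s = 0; s < S - 1; ++s) init_conv(n->sideC[s], n->ch[s], 1, 1, -4.0);
  init_conv(n->sideC[S - 1], n->ch[S - 1], 1, 1, -4.0);
  // fusion starts as the average of the side logits
  n->fuseC.W.set_size(n->K(), 1);
  n->fuseC.W.fill(1.0 / n->K());
  n->fuseC.b.set_size(1); n->fuseC.b.zeros();
  n->fuseC.init_state();
  if (cfg.mode == 1) {
    init_conv(n->fc1, 1, 1, 1); // resized below
    n->fc1.W.set_size(n->ch[S - 1], cfg.beta_hidden);
    for (uword i = 0; i < n->fc1.W.n_elem; ++i) n->fc1.W[i] = rnorm_he(n->ch[S - 1]);
    n->fc1.b.zeros(cfg.beta_hidden);
    n->fc1.init_state();
    n->fc2.W.zeros(cfg.beta_hidden, 1);
    n->fc2.b.set_size(1);
    // start at beta = 1 (no correction): sigmoid mode needs sigma(z) = 1/lambda
    if (cfg.beta_activation == 0) {
      n->fc2.b[0] = (cfg.lambda > 1.0) ? std::log(1.0 / (cfg.lambda - 1.0)) : 0.0;
    } else {
      n->fc2.b[0] = 1.0;
    }
    n->fc2.init_state();
    n->fc1.lr_scale = cfg.beta_lr_scale;
    n->fc2.lr_scale = cfg.beta_lr_scale;
  }
  register_params(*n);
  return n;
}

// -------------------------------------------------------------- forward pass

struct FwdCache {
  std::vector<RSUCache> encC, decC;
  std::vector<umat> poolArg;     // between top-level encoder stages
  std::vector<cube> encO, decO;  // block outputs
  std::vector<cube> sideRaw;     // side logits at native resolution
  std::vector<cube> sideUp;      // upsampled to output resolution
  cube fuseIn;                   // concat of sideUp (K slices)
  cube S0;
  vec gap; vec h1;               // beta head caches
  double z = 0.0, beta = 1.0;
  bool beta_forced = false;
};

static void net_fwd(Net& n, const cube& img, bool use_dropout,
                    double beta_override, FwdCache& C) {
  const int S = n.cfg.n_stages;
  const double rate = n.cfg.dropout_rate;
  C.encC.resize(S); C.decC.resize(S - 1); C.poolArg.resize(S - 1);
  C.encO.resize(S); C.decO.resize(S - 1);
  C.encO[0] = rsu_fwd(n.encB[0], img, use_dropout, rate, &C.encC[0]);
  for (int s = 1; s < S; ++s) {
    cube pooled = maxpool2_fwd(C.encO[s - 1], C.poolArg[s - 1]);
    C.encO[s] = rsu_fwd(n.encB[s], pooled, use_dropout, rate, &C.encC[s]);
  }
  // beta head off the deepest encoder block
  if (n.cfg.mode == 1 && beta_override <= 0) {
    const cube& bo = C.encO[S - 1];
    C.gap.set_size(bo.n_slices);
    for (uword c = 0; c < bo.n_slices; ++c) C.gap[c] = accu(bo.slice(c)) / (bo.n_rows * bo.n_cols);
    C.h1 = n.fc1.W.t() * C.gap + n.fc1.b;
    C.h1.transform([](double v) { return v > 0 ? v : 0.0; });
    C.z = as_scalar(n.fc2.W.t() * C.h1) + n.fc2.b[0];
    C.beta = (n.cfg.beta_activation == 0) ? n.cfg.lambda * sigmoid(C.z)
                                          : std::max(0.0, C.z);
    C.beta_forced = false;
  } else {
    C.beta = (beta_override > 0) ? beta_override : 1.0;
    C.beta_forced = true;
  }
  cube prev = C.encO[S - 1];
  for (int s = S - 2; s >= 0; --s) {
    cube up = up2_fwd(prev);
    cube cat = join_slices(up, C.encO[s]);
    C.decO[s] = rsu_fwd(n.decB[s], cat, use_dropout, rate, &C.decC[s]);
    prev = C.decO[s];
  }
  const int N = n.cfg.input_size;
  C.sideRaw.resize(n.K()); C.sideUp.resize(n.K());
  for (int s = 0; s < S - 1; ++s) {
    C.sideRaw[s] = conv1_fwd(C.decO[s], n.sideC[s]);
    C.sideUp[s] = up_to(C.sideRaw[s], N);
  }
  C.sideRaw[S - 1] = conv1_fwd(C.encO[S - 1], n.sideC[S - 1]);
  C.sideUp[S - 1] = up_to(C.sideRaw[S - 1], N);
  C.fuseIn.set_size(N, N, n.K());
  for (int k = 0; k < n.K(); ++k) C.fuseIn.slice(k) = C.sideUp[k].slice(0);
  C.S0 = conv1_fwd(C.fuseIn, n.fuseC);
}

// BCE of sigmoid(beta * S) against target T, summed over pixels; also returns
// dL/d(beta*S) = P - T and accumulates sum(S % (P - T)) for the beta gradient.
static double bce_and_grad(const mat& Smap, const mat& T, double beta,
                           mat& dS, double& dbeta_acc, bool want_grad) {
  mat P = Smap;
  P.transform([beta](double v) { return sigmoid(beta * v); });
  // numerically safe log terms
  const double eps = 1e-12;
  double loss = -accu(T % log(P + eps) + (1.0 - T) % log(1.0 - P + eps));
  if (want_grad) {
    mat diff = P - T;
    dbeta_acc += accu(Smap % diff);
    dS = beta * diff;
  }
  return loss;
}

// backward from side-map logit gradients through the whole trunk
static void net_bwd(Net& n, FwdCache& C, std::vector<mat>& dSide, mat& dS0,
                    double dbeta) {
  const int S = n.cfg.n_stages;
  const int N = n.cfg.input_size;
  // fusion backward: dS0 -> fuseIn grads, added to side-map grads
  cube dS0c(N, N, 1); dS0c.slice(0) = dS0;
  cube dFuseIn = conv1_bwd(C.fuseIn, n.fuseC, dS0c);
  std::vector<cube> dBlock(S - 1); // grads at decO[s]
  cube dBottleneck(C.encO[S - 1].n_rows, C.encO[S - 1].n_cols,
                   C.encO[S - 1].n_slices, fill::zeros);
  for (int k = 0; k < n.K(); ++k) {
    cube dUp(N, N, 1);
    dUp.slice(0) = dSide[k] + dFuseIn.slice(k);
    cube dRaw = down_from(dUp, C.sideRaw[k].n_rows);
    if (k < S - 1) {
      cube dIn = conv1_bwd(C.decO[k], n.sideC[k], dRaw);
      dBlock[k] = dIn;
    } else {
      dBottleneck += conv1_bwd(C.encO[S - 1], n.sideC[k], dRaw);
    }
  }
  // beta head backward
  if (n.cfg.mode == 1 && !C.beta_forced && dbeta != 0.0) {
    double dz;
    if (n.cfg.beta_activation == 0) {
      const double s = sigmoid(C.z);
      dz = dbeta * n.cfg.lambda * s * (1.0 - s);
    } else {
      dz = (C.z > 0) ? dbeta : 0.0;
    }
    n.fc2.gW += C.h1 * dz;
    n.fc2.gb[0] += dz;
    vec dh1 = n.fc2.W * dz;
    for (uword i = 0; i < dh1.n_elem; ++i) if (C.h1[i] <= 0) dh1[i] = 0;
    n.fc1.gW += C.gap * dh1.t();
    n.fc1.gb += dh1;
    vec dgap = n.fc1.W * dh1;
    const cube& bo = C.encO[S - 1];
    const double scale = 1.0 / (bo.n_rows * bo.n_cols);
    for (uword c = 0; c < bo.n_slices; ++c) dBottleneck.slice(c) += dgap[c] * scale;
  }
  // decoder blocks backward, shallowest first (reverse of forward order)
  cube dPrev; // gradient flowing to the previous (deeper) block output
  for (int s = 0; s <= S - 2; ++s) {
    cube dOut = dBlock[s];
    if (s > 0) dOut += dPrev;
    cube dCat = rsu_bwd(n.decB[s], C.decC[s], dOut);
    const int prev_ch = dCat.n_slices - n.ch[s];
    cube dUp = dCat.slices(0, prev_ch - 1);
    cube dSkip = dCat.slices(prev_ch, dCat.n_slices - 1);
    if (s == S - 2) {
      dBottleneck += up2_bwd(dUp, dUp.n_rows / 2, dUp.n_cols / 2);
    } else {
      dPrev = up2_bwd(dUp, dUp.n_rows / 2, dUp.n_cols / 2);
    }
    // store skip gradient into a per-encoder accumulator via dBlock reuse
    dBlock[s] = dSkip; // now holds gradient to encO[s] from the skip
  }
  // encoder blocks backward, deepest first
  cube dEnc = dBottleneck;
  for (int s = S - 1; s >= 0; --s) {
    if (s < S - 1) {
      // gradient from the pooling into this stage plus the skip gradient
      dEnc += dBlock[s];
    }
    cube dIn = rsu_bwd(n.encB[s], C.encC[s], dEnc);
    if (s > 0) {
      dEnc = maxpool2_bwd(dIn, C.poolArg[s - 1], C.encO[s - 1].n_rows,
                          C.encO[s - 1].n_cols);
    }
  }
}

static void adam_step(Net& n, double lr, double wd, int batch) {
  n.t_adam += 1;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1.0 - std::pow(b1, (double)n.t_adam);
  const double c2 = 1.0 - std::pow(b2, (double)n.t_adam);
  for (Param* p : n.params) {
    const double plr = lr * p->lr_scale;
    mat gW = p->gW / batch + wd * p->W;
    vec gb = p->gb / batch;
    p->mW = b1 * p->mW + (1 - b1) * gW;
    p->vW = b2 * p->vW + (1 - b2) * square(gW);
    p->W -= plr * (p->mW / c1) / (sqrt(p->vW / c2) + eps);
    p->mb = b1 * p->mb + (1 - b1) * gb;
    p->vb = b2 * p->vb + (1 - b2) * square(gb);
    p->b -= plr * (p->mb / c1) / (sqrt(p->vb / c2) + eps);
    p->zero_grad();
  }
}

// ------------------------------------------------------------------ R glue

static NetConfig config_from_list(Rcpp::List cfg) {
  NetConfig c;
  c.mode = Rcpp::as<std::string>(cfg["mode"]) == "sndm" ? 1 : 0;
  c.input_size = Rcpp::as<int>(cfg["input_size"]);
  c.n_stages = Rcpp::as<int>(cfg["n_stages"]);
  c.base_channels = Rcpp::as<int>(cfg["base_channels"]);
  c.channel_cap = Rcpp::as<int>(cfg["channel_cap"]);
  c.depths = Rcpp::as<std::vector<int>>(cfg["rsu_depths"]);
  c.dropout_rate = Rcpp::as<double>(cfg["dropout_rate"]);
  c.beta_activation =
    Rcpp::as<std::string>(cfg["beta_activation"]) == "relu" ? 1 : 0;
  c.lambda = Rcpp::as<double>(cfg["lambda"]);
  c.beta_hidden = Rcpp::as<int>(cfg["beta_hidden"]);
  c.beta_lr_scale = Rcpp::as<double>(cfg["beta_lr_scale"]);
  if ((int)c.depths.size() != 2 * c.n_stages - 1)
    Rcpp::stop("rsu_depths must have length 2*n_stages - 1");
  if (c.n_stages < 2) Rcpp::stop("n_stages must be >= 2");
  if (c.lambda <= 0) Rcpp::stop("lambda must be positive");
  return c;
}

// [[Rcpp::export]]
SEXP cpp_net_create(Rcpp::List cfg) {
  NetConfig c = config_from_list(cfg);
  Rcpp::XPtr<Net> ptr(build_net(c), true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_describe(SEXP net_ptr) {
  Rcpp::XPtr<Net> n(net_ptr);
  long np = 0;
  for (Param* p : n->params) np += p->W.n_elem + p->b.n_elem;
  return Rcpp::List::create(
    Rcpp::Named("n_blocks") = (int)(n->encB.size() + n->decB.size()),
    Rcpp::Named("n_side_outputs") = n->K(),
    Rcpp::Named("n_params") = (double)np,
    Rcpp::Named("channels") = n->ch,
    Rcpp::Named("mode") = n->cfg.mode == 1 ? "sndm" : "dm");
}

// [[Rcpp::export]]
Rcpp::List cpp_net_forward(SEXP net_ptr, const arma::cube& image,
                           bool dropout_active, double beta_override,
                           bool return_maps) {
  Rcpp::XPtr<Net> n(net_ptr);
  if ((int)image.n_rows != n->cfg.input_size ||
      (int)image.n_cols != n->cfg.input_size || image.n_slices != 3)
    Rcpp::stop("image must be %d x %d x 3", n->cfg.input_size, n->cfg.input_size);
  FwdCache C;
  double ov = beta_override;
  if (n->cfg.mode == 0) ov = 1.0; // dm mode: beta fixed at 1 by definition
  net_fwd(*n, image, dropout_active, ov, C);
  const double beta = C.beta;
  mat P0 = C.S0.slice(0);
  P0.transform([beta](double v) { return sigmoid(beta * v); });
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("P0") = P0,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("count") = accu(P0));
  if (return_maps) {
    Rcpp::List Smaps(n->K() + 1), Pmaps(n->K() + 1);
    Smaps[0] = C.S0.slice(0);
    Pmaps[0] = P0;
    for (int k = 0; k < n->K(); ++k) {
      mat Sk = C.sideUp[k].slice(0);
      mat Pk = Sk;
      Pk.transform([beta](double v) { return sigmoid(beta * v); });
      Smaps[k + 1] = Sk; Pmaps[k + 1] = Pk;
    }
    out["S"] = Smaps; out["P"] = Pmaps;
  }
  return out;
}

// One optimizer step on a mini-batch. Returns the loss breakdown summed over
// the batch: per-map BCE terms, the beta penalty, and their total.
// [[Rcpp::export]]
Rcpp::List cpp_net_train_batch(SEXP net_ptr, Rcpp::List images,
                               Rcpp::List targets, double lr,
                               double weight_decay, double penalty_weight,
                               bool penalty_only, bool update) {
  Rcpp::XPtr<Net> n(net_ptr);
  const int B = images.size();
  const int K = n->K();
  vec per_map(K + 1, fill::zeros);
  double penalty = 0.0;
  double beta_sum = 0.0;
  for (int b = 0; b < B; ++b) {
    cube img = Rcpp::as<cube>(images[b]);
    mat T = Rcpp::as<mat>(targets[b]);
    FwdCache C;
    net_fwd(*n, img, true, n->cfg.mode == 0 ? 1.0 : -1.0, C);
    const double beta = C.beta;
    beta_sum += beta;
    std::vector<mat> dSide(K);
    mat dS0;
    double dbeta_acc = 0.0;
    if (!penalty_only) {
      per_map[0] += bce_and_grad(C.S0.slice(0), T, beta, dS0, dbeta_acc, true);
      for (int k = 0; k < K; ++k)
        per_map[k + 1] += bce_and_grad(C.sideUp[k].slice(0), T, beta,
                                       dSide[k], dbeta_acc, true);
    } else {
      dS0.zeros(T.n_rows, T.n_cols);
      for (int k = 0; k < K; ++k) dSide[k].zeros(T.n_rows, T.n_cols);
    }
    double dbeta = dbeta_acc;
    if (n->cfg.mode == 1) {
      penalty += 0.5 * penalty_weight * std::pow(1.0 - beta, 2.0);
      dbeta += penalty_weight * (beta - 1.0);
    }
    net_bwd(*n, C, dSide, dS0, dbeta);
    if (!std::isfinite(accu(per_map) + penalty))
      Rcpp::stop("divergent loss (non-finite); lower the learning rate");
  }
  if (update) adam_step(*n, lr, weight_decay, B);
  return Rcpp::List::create(
    Rcpp::Named("per_map_bce") = per_map,
    Rcpp::Named("penalty") = penalty,
    Rcpp::Named("total") = accu(per_map) + penalty,
    Rcpp::Named("mean_beta") = beta_sum / B);
}

// [[Rcpp::export]]
arma::vec cpp_net_get_params(SEXP net_ptr) {
  Rcpp::XPtr<Net> n(net_ptr);
  long np = 0;
  for (Param* p : n->params) np += p->W.n_elem + p->b.n_elem;
  vec out(np);
  long k = 0;
  for (Param* p : n->params) {
    std::memcpy(out.memptr() + k, p->W.memptr(), sizeof(double) * p->W.n_elem);
    k += p->W.n_elem;
    std::memcpy(out.memptr() + k, p->b.memptr(), sizeof(double) * p->b.n_elem);
    k += p->b.n_elem;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_params(SEXP net_ptr, const arma::vec& theta) {
  Rcpp::XPtr<Net> n(net_ptr);
  long np = 0;
  for (Param* p : n->params) np += p->W.n_elem + p->b.n_elem;
  if ((long)theta.n_elem != np) Rcpp::stop("parameter vector has wrong length");
  long k = 0;
  for (Param* p : n->params) {
    std::memcpy(p->W.memptr(), theta.memptr() + k, sizeof(double) * p->W.n_elem);
    k += p->W.n_elem;
    std::memcpy(p->b.memptr(), theta.memptr() + k, sizeof(double) * p->b.n_elem);
    k += p->b.n_elem;
  }
}

// Accumulated gradient vector in the same layout as cpp_net_get_params
// (populated by cpp_net_train_batch with update = FALSE). Diagnostic.
// [[Rcpp::export]]
arma::vec cpp_net_get_grads(SEXP net_ptr) {
  Rcpp::XPtr<Net> n(net_ptr);
  long np = 0;
  for (Param* p : n->params) np += p->W.n_elem + p->b.n_elem;
  vec out(np);
  long k = 0;
  for (Param* p : n->params) {
    std::memcpy(out.memptr() + k, p->gW.memptr(), sizeof(double) * p->gW.n_elem);
    k += p->gW.n_elem;
    std::memcpy(out.memptr() + k, p->gb.memptr(), sizeof(double) * p->gb.n_elem);
    k += p->gb.n_elem;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_net_zero_grads(SEXP net_ptr) {
  Rcpp::XPtr<Net> n(net_ptr);
  for (Param* p : n->params) p->zero_grad();
}

// [[Rcpp::export]]
void cpp_net_zero_params(SEXP net_ptr) {
  Rcpp::XPtr<Net> n(net_ptr);
  for (Param* p : n->params) { p->W.zeros(); p->b.zeros(); }
}

// Adjust the beta-head learning-rate multiplier at run time (0 freezes it).
// [[Rcpp::export]]
void cpp_net_set_beta_lr_scale(SEXP net_ptr, double s) {
  Rcpp::XPtr<Net> n(net_ptr);
  if (n->cfg.mode != 1) return;
  n->fc1.lr_scale = s;
  n->fc2.lr_scale = s;
}

// Surgically pin the beta-head pre-activation to a constant `z` by zeroing
// the final FC weights and setting its bias.
// [[Rcpp::export]]
void cpp_net_fix_beta_preactivation(SEXP net_ptr, double z) {
  Rcpp::XPtr<Net> n(net_ptr);
  if (n->cfg.mode != 1) Rcpp::stop("model has no beta head (dm mode)");
  n->fc2.W.zeros();
  n->fc2.b[0] = z;
}

// [[Rcpp::export]]
double cpp_beta_activation(double z, double lambda, std::string type) {
  if (type == "relu") return std::max(0.0, z);
  return lambda * sigmoid(z);
}

// [[Rcpp::export]]
arma::mat cpp_apply_normalization(const arma::mat& S, double beta) {
  mat out = S;
  out.transform([beta](double v) { return sigmoid(beta * v); });
  return out;
}
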