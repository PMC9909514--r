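// Compact CNN for 2-D log-Mel segments: conv(3x3,same)+ReLU+maxpool blocks,
// dense head with dropout, sigmoid output, Adam, validation-accuracy early
// stopping. Single precision, single threaded.
//
// Convolution runs over a zero-padded activation layout (channels x
// (Hp*Wp*batch), one padded spatial block per sample, spatial index
// i + j*Hp): the one-pixel ring makes every 3x3 offset a constant column
// shift, so the im2col gather is a plain block copy and each layer is a
// single GEMM. All large buffers live in a workspace reused across
// minibatches.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

struct PoolSpec { int sh, sw; };

struct Arch {
  int H, W;                 // input mel bands x frames
  std::vector<int> chan;    // conv channels per block
  int k;                    // kernel size (3 assumed by the shift scheme)
  PoolSpec pool;            // pooling strides (window fixed 2x2)
  std::vector<int> dense;   // hidden dense sizes
  float dropout;
};

inline int pool_out(int d, int stride) { return (d - 2) / stride + 1; }

Arch arch_from_list(const Rcpp::List& a) {
  Arch ar;
  ar.H = Rcpp::as<int>(a["input_mels"]);
  ar.W = Rcpp::as<int>(a["input_frames"]);
  ar.chan = Rcpp::as<std::vector<int>>(a["conv_channels"]);
  ar.k = Rcpp::as<int>(a["kernel"]);
  if (ar.k != 3) Rcpp::stop("only 3x3 kernels are supported");
  Rcpp::IntegerVector ps = a["pool_stride"];
  ar.pool = PoolSpec{ps[0], ps[1]};
  ar.dense = Rcpp::as<std::vector<int>>(a["dense"]);
  ar.dropout = (float)Rcpp::as<double>(a["dropout"]);
  return ar;
}

void block_dims(const Arch& ar, std::vector<int>& Hs, std::vector<int>& Ws) {
  int h = ar.H, w = ar.W;
  Hs = {h}; Ws = {w};
  for (size_t i = 0; i < ar.chan.size(); ++i) {
    h = pool_out(h, ar.pool.sh);
    w = pool_out(w, ar.pool.sw);
    if (h < 1 || w < 1)
      Rcpp::stop("pooled feature map collapses below 1x1 at block %d",
                 (int)i + 1);
    Hs.push_back(h); Ws.push_back(w);
  }
}

// zero the one-pixel ring of every sample's padded block
void zero_rings(fmat& M, int H, int W, int B) {
  const int Hp = H + 2, Wp = W + 2;
  const uword HpWp = (uword)Hp * Wp;
  for (int b = 0; b < B; ++b) {
    const uword off = (uword)b * HpWp;
    M.cols(off, off + Hp - 1).zeros();                       // j = 0
    M.cols(off + (uword)(Wp - 1) * Hp, off + HpWp - 1).zeros();  // j = Wp-1
    for (int j = 1; j < Wp - 1; ++j) {
      M.col(off + (uword)j * Hp).zeros();          // i = 0
      M.col(off + (uword)j * Hp + Hp - 1).zeros(); // i = Hp-1
    }
  }
}

// gather the padded activation into a (9*Cin) x n col matrix whose row
// block d holds the offset-d neighbour of every column; one-pixel padding
// rings make every interior read a constant column shift
void gather_col(const fmat& Ap, int Cin, int Hp, fmat& col) {
  const uword n = Ap.n_cols;
  col.set_size((uword)9 * Cin, n);
  for (int d = 0; d < 9; ++d) {
    const int di = d / 3, dj = d % 3;
    const long delta = (di - 1) + (long)(dj - 1) * Hp;
    const uword lo = delta < 0 ? (uword)(-delta) : 0;
    const uword hi = n - 1 - (delta > 0 ? (uword)delta : 0);
    const uword r0 = (uword)d * Cin;
    for (uword j = 0; j < lo; ++j)
      std::memset(col.colptr(j) + r0, 0, sizeof(float) * Cin);
    for (uword j = hi + 1; j < n; ++j)
      std::memset(col.colptr(j) + r0, 0, sizeof(float) * Cin);
    for (uword j = lo; j <= hi; ++j)
      std::memcpy(col.colptr(j) + r0, Ap.colptr(j + delta),
                  sizeof(float) * Cin);
  }
}

// single-channel gather into a transposed (n x 9) col: each offset is one
// large shifted copy of the 1 x n activation
void gather_col_1ch(const fmat& Ap, int Hp, fmat& colT) {
  const uword n = Ap.n_cols;
  colT.set_size(n, 9);
  const float* a = Ap.memptr();
  for (int d = 0; d < 9; ++d) {
    const int di = d / 3, dj = d % 3;
    const long delta = (di - 1) + (long)(dj - 1) * Hp;
    const uword lo = delta < 0 ? (uword)(-delta) : 0;
    const uword hi = n - 1 - (delta > 0 ? (uword)delta : 0);
    float* c = colT.colptr(d);
    if (lo > 0) std::memset(c, 0, sizeof(float) * lo);
    if (hi + 1 < n) std::memset(c + hi + 1, 0, sizeof(float) * (n - hi - 1));
    std::memcpy(c + lo, a + lo + delta, sizeof(float) * (hi - lo + 1));
  }
}

inline void bias_relu(fmat& Op, const fvec& bias) {
  const uword C = Op.n_rows, n = Op.n_cols;
  const float* b = bias.memptr();
  for (uword j = 0; j < n; ++j) {
    float* o = Op.colptr(j);
    for (uword c = 0; c < C; ++c) {
      const float v = o[c] + b[c];
      o[c] = v > 0 ? v : 0.0f;
    }
  }
}

// conv forward: Ap (Cin x HpWp*B, rings zero) -> Op (Cout x HpWp*B);
// weight Wt is Cout x 9*Cin with offset-major column blocks; col is the
// gathered input, cached for the backward pass (transposed when Cin = 1)
void conv_forward(const fmat& Wt, const fvec& bias, const fmat& Ap,
                  int Cin, int H, int W, int B, fmat& Op, fmat& col) {
  if (Cin == 1) {
    gather_col_1ch(Ap, H + 2, col);
    Op = Wt * col.t();
  } else {
    gather_col(Ap, Cin, H + 2, col);
    Op = Wt * col;
  }
  bias_relu(Op, bias);
  zero_rings(Op, H, W, B);
}

// conv backward: dZ (Cout x HpWp*B, rings zero, relu already applied)
void conv_backward(const fmat& Wt, const fmat& col, const fmat& dZ,
                   int Cin, int H, int W, int B,
                   fmat& dW, fvec& db, fmat* dAp) {
  const int Hp = H + 2;
  const bool transposed = Cin == 1 && col.n_cols == 9;
  const uword n = transposed ? col.n_rows : col.n_cols;
  dW = transposed ? fmat(dZ * col) : fmat(dZ * col.t());
  db = arma::sum(dZ, 1);
  if (dAp) {
    const fmat dcol = Wt.t() * dZ;
    for (int d = 0; d < 9; ++d) {
      const int di = d / 3, dj = d % 3;
      const long delta = (di - 1) + (long)(dj - 1) * Hp;
      const uword lo = delta < 0 ? (uword)(-delta) : 0;
      const uword hi = n - 1 - (delta > 0 ? (uword)delta : 0);
      dAp->cols(lo + delta, hi + delta) +=
        dcol.rows((uword)d * Cin, (uword)(d + 1) * Cin - 1).cols(lo, hi);
    }
    zero_rings(*dAp, H, W, B);
  }
}

// maxpool padded->padded; argmax holds the source column of the padded
// input for each (channel, padded-output column) pair (interior only)
void maxpool(const fmat& Ap, int C, int H, int W, int B, PoolSpec p,
             fmat& Op, arma::umat& argmax, int& Ho, int& Wo) {
  Ho = pool_out(H, p.sh);
  Wo = pool_out(W, p.sw);
  const int Hp = H + 2, Hpo = Ho + 2, Wpo = Wo + 2;
  const uword HpWp = (uword)Hp * (W + 2), HpWpo = (uword)Hpo * Wpo;
  Op.set_size(C, HpWpo * B);
  argmax.set_size(C, HpWpo * B);
  for (int b = 0; b < B; ++b) {
    const uword off_in = (uword)b * HpWp, off_out = (uword)b * HpWpo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const uword so = off_out + (io + 1) + (uword)(jo + 1) * Hpo;
        const int i0 = io * p.sh + 1, j0 = jo * p.sw + 1;
        const uword c00 = off_in + i0 + (uword)j0 * Hp;
        const uword cand[4] = {c00, c00 + 1, c00 + Hp, c00 + Hp + 1};
        for (int c = 0; c < C; ++c) {
          float best = Ap(c, cand[0]);
          uword bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            const float v = Ap(c, cand[q]);
            if (v > best) { best = v; bi = cand[q]; }
          }
          Op(c, so) = best;
          argmax(c, so) = bi;
        }
      }
    }
  }
  zero_rings(Op, Ho, Wo, B);
}

struct Params {
  std::vector<fmat> W;
  std::vector<fvec> b;
};

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  long t = 0;
  void init(const Params& p) {
    for (auto& w : p.W) { mW.emplace_back(arma::size(w), arma::fill::zeros);
                          vW.emplace_back(arma::size(w), arma::fill::zeros); }
    for (auto& bb : p.b) { mb.emplace_back(arma::size(bb), arma::fill::zeros);
                           vb.emplace_back(arma::size(bb), arma::fill::zeros); }
  }
};

void adam_step(Params& p, const Params& g, AdamState& st, float lr) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  st.t += 1;
  const float c1 = 1.0f - std::pow(b1, (float)st.t);
  const float c2 = 1.0f - std::pow(b2, (float)st.t);
  for (size_t i = 0; i < p.W.size(); ++i) {
    st.mW[i] = b1 * st.mW[i] + (1 - b1) * g.W[i];
    st.vW[i] = b2 * st.vW[i] + (1 - b2) * arma::square(g.W[i]);
    p.W[i] -= lr * (st.mW[i] / c1) / (arma::sqrt(st.vW[i] / c2) + eps);
    st.mb[i] = b1 * st.mb[i] + (1 - b1) * g.b[i];
    st.vb[i] = b2 * st.vb[i] + (1 - b2) * arma::square(g.b[i]);
    p.b[i] -= lr * (st.mb[i] / c1) / (arma::sqrt(st.vb[i] / c2) + eps);
  }
}

Params params_from_list(const Rcpp::List& wl) {
  Params p;
  Rcpp::List Ws = wl["W"], bs = wl["b"];
  for (int i = 0; i < Ws.size(); ++i) {
    p.W.push_back(arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(Ws[i])));
    p.b.push_back(arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(bs[i])));
  }
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  Rcpp::List Ws(p.W.size()), bs(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    Ws[i] = Rcpp::wrap(arma::conv_to<arma::mat>::from(p.W[i]));
    bs[i] = Rcpp::wrap(arma::conv_to<arma::vec>::from(p.b[i]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

// per-batch buffers, reused across minibatches of equal size
struct Cache {
  std::vector<fmat> cols;       // gathered conv inputs (9*Cin x cols)
  std::vector<fmat> relu_out;   // padded post-relu conv outputs
  std::vector<fmat> pooled;     // padded pooled outputs
  std::vector<arma::umat> pool_arg;
  std::vector<fmat> dZ, dA;     // backward scratch
  std::vector<int> Hs, Ws;
  fmat pad0;                    // padded input activation
  fmat flat;
  std::vector<fmat> dense_in;
  std::vector<fmat> drop_mask;
  void ensure(int nblk, int ndense) {
    if ((int)cols.size() != nblk) {
      cols.resize(nblk); relu_out.resize(nblk); pooled.resize(nblk);
      pool_arg.resize(nblk); dZ.resize(nblk); dA.resize(nblk);
    }
    if ((int)dense_in.size() != ndense + 1) {
      dense_in.resize(ndense + 1); drop_mask.resize(ndense);
    }
  }
};

// Xb: (H*W) x B plain segments (index i + j*H); fills padded activation
void pad_input(const fmat& Xb, int H, int W, int B, fmat& A) {
  const int Hp = H + 2;
  const uword HpWp = (uword)Hp * (W + 2);
  A.zeros(1, HpWp * B);
  for (int b = 0; b < B; ++b) {
    const uword off = (uword)b * HpWp;
    for (int j = 0; j < W; ++j)
      std::memcpy(A.colptr(off + 1 + (uword)(j + 1) * Hp),
                  Xb.colptr(b) + (uword)j * H, sizeof(float) * H);
  }
}

fvec forward(const Params& p, const Arch& ar, const fmat& Xb, int B,
             bool train, std::mt19937* rng, Cache& ws) {
  const int nblk = (int)ar.chan.size();
  const int ndense = (int)ar.dense.size();
  block_dims(ar, ws.Hs, ws.Ws);
  ws.ensure(nblk, ndense);
  pad_input(Xb, ar.H, ar.W, B, ws.pad0);
  int C = 1;
  for (int l = 0; l < nblk; ++l) {
    const fmat& A = l == 0 ? ws.pad0 : ws.pooled[l - 1];
    conv_forward(p.W[l], p.b[l], A, C, ws.Hs[l], ws.Ws[l], B,
                 ws.relu_out[l], ws.cols[l]);
    int Ho, Wo;
    maxpool(ws.relu_out[l], ar.chan[l], ws.Hs[l], ws.Ws[l], B, ar.pool,
            ws.pooled[l], ws.pool_arg[l], Ho, Wo);
    C = ar.chan[l];
  }
  // flatten interior: per sample, vector index c + (i + j*H_last)*C
  const fmat& A = ws.pooled[nblk - 1];
  const int Hl = ws.Hs[nblk], Wl = ws.Ws[nblk], Hpl = Hl + 2;
  const uword HpWpl = (uword)Hpl * (Wl + 2);
  const int flat = C * Hl * Wl;
  fmat& F = ws.dense_in[0];
  F.set_size(flat, B);
  for (int b = 0; b < B; ++b) {
    const uword off = (uword)b * HpWpl;
    for (int j = 0; j < Wl; ++j)
      for (int i = 0; i < Hl; ++i) {
        const uword src = off + (i + 1) + (uword)(j + 1) * Hpl;
        for (int c = 0; c < C; ++c)
          F((uword)c + (uword)(i + j * Hl) * C, b) = A(c, src);
      }
  }
  ws.flat = F;
  std::bernoulli_distribution keep(1.0 - ar.dropout);
  for (int d = 0; d < ndense; ++d) {
    fmat Z = p.W[nblk + d] * ws.dense_in[d];
    Z.each_col() += p.b[nblk + d];
    Z.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (train && ar.dropout > 0 && rng) {
      fmat mask(arma::size(Z));
      const float scale = 1.0f / (1.0f - ar.dropout);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = keep(*rng) ? scale : 0.0f;
      Z %= mask;
      ws.drop_mask[d] = std::move(mask);
    } else {
      ws.drop_mask[d].reset();
    }
    ws.dense_in[d + 1] = std::move(Z);
  }
  fmat logit = p.W[nblk + ndense] * ws.dense_in[ndense];
  logit.each_col() += p.b[nblk + ndense];
  fvec out(B);
  for (int b = 0; b < B; ++b)
    out(b) = 1.0f / (1.0f + std::exp(-logit(0, b)));
  return out;
}

void backward(const Params& p, const Arch& ar, Cache& ws,
              const fvec& prob, const fvec& y, int B, Params& g) {
  const int nblk = (int)ar.chan.size();
  const int ndense = (int)ar.dense.size();
  g.W.resize(p.W.size());
  g.b.resize(p.b.size());
  fmat dlogit(1, B);
  for (int b = 0; b < B; ++b) dlogit(0, b) = (prob(b) - y(b)) / B;
  const fmat& hlast = ws.dense_in[ndense];
  g.W[nblk + ndense] = dlogit * hlast.t();
  g.b[nblk + ndense] = arma::sum(dlogit, 1);
  fmat dH = p.W[nblk + ndense].t() * dlogit;
  for (int d = ndense - 1; d >= 0; --d) {
    const fmat& post = ws.dense_in[d + 1];
    if (ws.drop_mask[d].n_elem > 0) dH %= ws.drop_mask[d];
    dH %= arma::conv_to<fmat>::from(post > 0);
    g.W[nblk + d] = dH * ws.dense_in[d].t();
    g.b[nblk + d] = arma::sum(dH, 1);
    dH = p.W[nblk + d].t() * dH;
  }
  // unflatten into the padded pooled layout of the last block
  const int Hl = ws.Hs[nblk], Wl = ws.Ws[nblk], Hpl = Hl + 2;
  const uword HpWpl = (uword)Hpl * (Wl + 2);
  const int C = ar.chan[nblk - 1];
  fmat& dAlast = ws.dA[nblk - 1];
  dAlast.zeros(C, HpWpl * B);
  for (int b = 0; b < B; ++b) {
    const uword off = (uword)b * HpWpl;
    for (int j = 0; j < Wl; ++j)
      for (int i = 0; i < Hl; ++i) {
        const uword dst = off + (i + 1) + (uword)(j + 1) * Hpl;
        for (int c = 0; c < C; ++c)
          dAlast(c, dst) = dH((uword)c + (uword)(i + j * Hl) * C, b);
      }
  }
  for (int l = nblk - 1; l >= 0; --l) {
    const fmat& Z = ws.relu_out[l];
    const fmat& dA = ws.dA[l];
    fmat& dZ = ws.dZ[l];
    dZ.zeros(arma::size(Z));
    const arma::umat& arg = ws.pool_arg[l];
    // scatter through the pooling argmax (interior of dA only; rings zero)
    for (uword j = 0; j < dA.n_cols; ++j)
      for (uword c = 0; c < dA.n_rows; ++c) {
        const float v = dA(c, j);
        if (v != 0.0f) dZ(c, arg(c, j)) += v;
      }
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (Z(i) <= 0) dZ(i) = 0.0f;
    const int Cin = l > 0 ? ar.chan[l - 1] : 1;
    if (l > 0) {
      fmat& dprev = ws.dA[l - 1];
      dprev.zeros(Cin, ws.cols[l].n_cols);
      conv_backward(p.W[l], ws.cols[l], dZ, Cin, ws.Hs[l],
                    ws.Ws[l], B, g.W[l], g.b[l], &dprev);
    } else {
      conv_backward(p.W[l], ws.cols[l], dZ, Cin, ws.Hs[l],
                    ws.Ws[l], B, g.W[l], g.b[l], nullptr);
    }
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(Rcpp::List arch, int seed) {
  Arch ar = arch_from_list(arch);
  std::vector<int> Hs, Ws;
  block_dims(ar, Hs, Ws);
  std::mt19937 rng((unsigned)seed);
  Params p;
  int cin = 1;
  const int kk = ar.k * ar.k;
  auto he = [&](int fan_in) {
    return std::normal_distribution<float>(0.0f, std::sqrt(2.0f / fan_in));
  };
  for (size_t l = 0; l < ar.chan.size(); ++l) {
    auto dist = he(kk * cin);
    fmat w(ar.chan[l], kk * cin);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = dist(rng);
    p.W.push_back(w);
    p.b.push_back(fvec(ar.chan[l], arma::fill::zeros));
    cin = ar.chan[l];
  }
  int prev = cin * Hs.back() * Ws.back();
  for (size_t d = 0; d < ar.dense.size(); ++d) {
    auto dist = he(prev);
    fmat w(ar.dense[d], prev);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = dist(rng);
    p.W.push_back(w);
    p.b.push_back(fvec(ar.dense[d], arma::fill::zeros));
    prev = ar.dense[d];
  }
  auto dist = he(prev);
  fmat w(1, prev);
  for (uword i = 0; i < w.n_elem; ++i) w(i) = dist(rng);
  p.W.push_back(w);
  p.b.push_back(fvec(1, arma::fill::zeros));
  return params_to_list(p);
}

// mean-BCE gradient at the given weights (dropout inactive); testing hook
// [[Rcpp::export]]
Rcpp::List cpp_cnn_grad(Rcpp::List weights, Rcpp::List arch,
                        Rcpp::NumericMatrix X, Rcpp::NumericVector y) {
  Arch ar = arch_from_list(arch);
  ar.dropout = 0.0f;
  Params p = params_from_list(weights);
  fmat Xf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X));
  fvec yf = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(y));
  const int B = (int)Xf.n_cols;
  Cache ws;
  fvec pr = forward(p, ar, Xf, B, true, nullptr, ws);
  Params g;
  backward(p, ar, ws, pr, yf, B, g);
  return params_to_list(g);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_predict(Rcpp::List weights, Rcpp::List arch,
                                    Rcpp::NumericMatrix X, int batch = 64) {
  Arch ar = arch_from_list(arch);
  Params p = params_from_list(weights);
  fmat Xf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X));
  const uword N = Xf.n_cols;
  Rcpp::NumericVector out(N);
  Cache ws;
  for (uword lo = 0; lo < N; lo += batch) {
    uword hi = std::min(N, lo + (uword)batch);
    fmat Xb = Xf.cols(lo, hi - 1);
    fvec pr = forward(p, ar, Xb, (int)(hi - lo), false, nullptr, ws);
    for (uword i = lo; i < hi; ++i) out[i] = pr(i - lo);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List weights, Rcpp::List arch,
                         Rcpp::NumericMatrix Xtr, Rcpp::NumericVector ytr,
                         Rcpp::NumericMatrix Xval, Rcpp::NumericVector yval,
                         int epochs, int batch, double lr, int patience,
                         int seed, bool verbose = false) {
  Arch ar = arch_from_list(arch);
  Params p = params_from_list(weights);
  AdamState st; st.init(p);
  std::mt19937 rng((unsigned)seed);
  fmat Xf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(Xtr));
  fvec yf = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(ytr));
  fmat Xv = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(Xval));
  fvec yv = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(yval));
  const uword N = Xf.n_cols, Nv = Xv.n_cols;
  std::vector<uword> idx(N);
  std::iota(idx.begin(), idx.end(), 0);

  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  Cache ws, ws_val;
  Params g;
  Params best = p;
  double best_val = -1.0, best_vloss = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double lsum = 0, acc = 0; uword nseen = 0;
    for (uword lo = 0; lo < N; lo += batch) {
      uword hi = std::min(N, lo + (uword)batch);
      int B = (int)(hi - lo);
      fmat Xb(Xf.n_rows, B);
      fvec yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.col(b) = Xf.col(idx[lo + b]);
        yb(b) = yf(idx[lo + b]);
      }
      fvec pr = forward(p, ar, Xb, B, true, &rng, ws);
      for (int b = 0; b < B; ++b) {
        float pb = std::min(std::max(pr(b), 1e-7f), 1.0f - 1e-7f);
        lsum += -(yb(b) * std::log(pb) + (1 - yb(b)) * std::log(1 - pb));
        acc += ((pr(b) >= 0.5f) == (yb(b) >= 0.5f));
      }
      nseen += B;
      backward(p, ar, ws, pr, yb, B, g);
      adam_step(p, g, st, (float)lr);
    }
    tr_loss.push_back(lsum / nseen);
    tr_acc.push_back(acc / nseen);
    double vl = 0, va = 0;
    for (uword lo = 0; lo < Nv; lo += batch) {
      uword hi = std::min(Nv, lo + (uword)batch);
      int B = (int)(hi - lo);
      fmat Xb = Xv.cols(lo, hi - 1);
      fvec pr = forward(p, ar, Xb, B, false, nullptr, ws_val);
      for (int b = 0; b < B; ++b) {
        float pb = std::min(std::max(pr(b), 1e-7f), 1.0f - 1e-7f);
        float yb = yv(lo + b);
        vl += -(yb * std::log(pb) + (1 - yb) * std::log(1 - pb));
        va += ((pr(b) >= 0.5f) == (yb >= 0.5f));
      }
    }
    vl /= std::max<uword>(Nv, 1);
    va /= std::max<uword>(Nv, 1);
    va_loss.push_back(vl);
    va_acc.push_back(va);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep << " loss " << tr_loss.back()
                  << " acc " << tr_acc.back() << " val_acc " << va << "\n";
    // best validation accuracy, ties broken by validation loss, so a
    // small validation set saturating early does not freeze weights
    if (va > best_val + 1e-9 ||
        (std::abs(va - best_val) <= 1e-9 && vl < best_vloss - 1e-6)) {
      best_val = va; best_vloss = vl; best = p; best_epoch = ep; bad = 0;
    } else if (++bad >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List hist = Rcpp::List::create(
    Rcpp::Named("epoch") = Rcpp::seq_len((int)tr_loss.size()),
    Rcpp::Named("train_loss") = tr_loss,
    Rcpp::Named("train_acc") = tr_acc,
    Rcpp::Named("val_loss") = va_loss,
    Rcpp::Named("val_acc") = va_acc);
  return Rcpp::List::create(
    Rcpp::Named("weights") = params_to_list(best),
    Rcpp::Named("history") = hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = (int)tr_loss.size());
}
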