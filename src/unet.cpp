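// A compact trainable U-Net implementation used by the classification,
// segmentation and branch-point decision modules. Feature maps are stored
// as (B*H*W x C) matrices (rows: batch-major, column-major spatial order
// within a sample; columns: channels). Convolutions are im2col + GEMM.
//
// Building block ("convBlock"): 3x3 padded convolution -> batch
// normalisation -> leaky ReLU with negative slope 0.1
// (leakyReLU(x) = max(x,0) - 0.1*max(-x,0)).
//
// The core is a depth-4 encoder/decoder with skip connections; feature
// widths are base*2^level (the full-size reference uses base = 64, i.e.
// 64..1024; smaller bases are used for desk-scale training). Heads:
//   map   - 1x1 convolution + elementwise logistic -> per-pixel trackness
//   class - global average pool + dense + softmax   -> 2 class probabilities
// Training minimises per-pixel (or per-entry) cross entropy
// CE(t,o) = -(t ln o + (1-t) ln(1-o)) averaged over all output entries,
// with Adam (beta1 0.9, beta2 0.999).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::XPtr;

static const double CE_EPS = 1e-7;

struct Adam {
  mat m, v;
  void init(const mat& w) { m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols); }
  void step(mat& w, const mat& g, double lr, long t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * square(g);
    double c1 = 1.0 - std::pow(0.9, (double)t);
    double c2 = 1.0 - std::pow(0.999, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8);
  }
};

static mat im2col3(const mat& X, int B, int H, int W) {
  int HW = H * W, C = X.n_cols;
  mat M(B * HW, 9 * C);
  for (int o = 0; o < 9; ++o) {
    int dh = o % 3 - 1, dw = o / 3 - 1;
    for (int ch = 0; ch < C; ++ch) {
      double* dst = M.colptr(o * C + ch);
      const double* src = X.colptr(ch);
      for (int b = 0; b < B; ++b) {
        const double* sb = src + (size_t)b * HW;
        double* db = dst + (size_t)b * HW;
        for (int w = 0; w < W; ++w) {
          int w2 = w + dw;
          if (w2 < 0 || w2 >= W) {
            for (int h = 0; h < H; ++h) db[w * H + h] = 0.0;
            continue;
          }
          for (int h = 0; h < H; ++h) {
            int h2 = h + dh;
            db[w * H + h] = (h2 < 0 || h2 >= H) ? 0.0 : sb[w2 * H + h2];
          }
        }
      }
    }
  }
  return M;
}

static mat col2im3(const mat& G, int B, int H, int W, int C) {
  int HW = H * W;
  mat X(B * HW, C, fill::zeros);
  for (int o = 0; o < 9; ++o) {
    int dh = o % 3 - 1, dw = o / 3 - 1;
    for (int ch = 0; ch < C; ++ch) {
      const double* g = G.colptr(o * C + ch);
      double* dst = X.colptr(ch);
      for (int b = 0; b < B; ++b) {
        const double* gb = g + (size_t)b * HW;
        double* db = dst + (size_t)b * HW;
        for (int w = 0; w < W; ++w) {
          int w2 = w + dw;
          if (w2 < 0 || w2 >= W) continue;
          for (int h = 0; h < H; ++h) {
            int h2 = h + dh;
            if (h2 >= 0 && h2 < H) db[w2 * H + h2] += gb[w * H + h];
          }
        }
      }
    }
  }
  return X;
}

struct Conv {  // 3x3 padded convolution
  int cin, cout;
  mat W; rowvec b;
  Adam aW, ab;
  mat cacheM;
  int cB, cH, cW;
  void init(int ci, int co, std::mt19937& rng) {
    cin = ci; cout = co;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (9.0 * ci)));
    W.set_size(9 * ci, co);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(co);
    aW.init(W); mat bb = conv_to<mat>::from(b); ab.init(bb);
  }
  mat forward(const mat& x, int B, int H, int Wd, bool keep) {
    mat M = im2col3(x, B, H, Wd);
    mat y = M * W;
    y.each_row() += b;
    if (keep) { cacheM = std::move(M); cB = B; cH = H; cW = Wd; }
    return y;
  }
  mat backward(const mat& gy, double lr, long t) {
    mat gW = cacheM.t() * gy;
    rowvec gb = sum(gy, 0);
    mat gM = gy * W.t();
    mat gx = col2im3(gM, cB, cH, cW, cin);
    cacheM.reset();
    aW.step(W, gW, lr, t);
    mat bb = conv_to<mat>::from(b), gbb = conv_to<mat>::from(gb);
    ab.step(bb, gbb, lr, t);
    b = bb.row(0);
    return gx;
  }
};

struct BN {
  rowvec g, beta, rmean, rvar;
  Adam ag, ab;
  mat xhat; rowvec istd;
  void init(int c) {
    g.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
    mat gg = conv_to<mat>::from(g); ag.init(gg); ab.init(gg);
  }
  mat forward(const mat& x, bool train) {
    if (train) {
      rowvec m = mean(x, 0);
      rowvec v = mean(square(x.each_row() - m), 0);
      istd = 1.0 / sqrt(v + 1e-5);
      xhat = (x.each_row() - m).eval().each_row() % istd;
      rmean = 0.9 * rmean + 0.1 * m;
      rvar = 0.9 * rvar + 0.1 * v;
      mat y = xhat.each_row() % g;
      y.each_row() += beta;
      return y;
    }
    rowvec is = 1.0 / sqrt(rvar + 1e-5);
    mat y = (x.each_row() - rmean).eval().each_row() % (is % g);
    y.each_row() += beta;
    return y;
  }
  mat backward(const mat& gy, double lr, long t) {
    double n = (double)gy.n_rows;
    rowvec gg = sum(gy % xhat, 0);
    rowvec gbe = sum(gy, 0);
    mat gx = gy.each_row() % g;
    rowvec s1 = sum(gx, 0);
    rowvec s2 = sum(gx % xhat, 0);
    gx = (gx * n - xhat.each_row() % s2);
    gx.each_row() -= s1;
    gx.each_row() %= (istd / n);
    xhat.reset();
    mat gm = conv_to<mat>::from(g), ggm = conv_to<mat>::from(gg);
    ag.step(gm, ggm, lr, t); g = gm.row(0);
    mat bm = conv_to<mat>::from(beta), gbm = conv_to<mat>::from(gbe);
    ab.step(bm, gbm, lr, t); beta = bm.row(0);
    return gx;
  }
};

struct Relu {
  mat mask;
  mat forward(const mat& x, bool keep) {
    mat y = x;
    mat mk(x.n_rows, x.n_cols);
    for (uword i = 0; i < x.n_elem; ++i) {
      if (x(i) >= 0) mk(i) = 1.0;
      else { y(i) = 0.1 * x(i); mk(i) = 0.1; }
    }
    if (keep) mask = std::move(mk);
    return y;
  }
  mat backward(const mat& gy) { mat gx = gy % mask; mask.reset(); return gx; }
};

struct ConvBlock {
  Conv conv; BN bn; Relu relu;
  void init(int ci, int co, std::mt19937& rng) { conv.init(ci, co, rng); bn.init(co); }
  mat forward(const mat& x, int B, int H, int W, bool train) {
    mat y = conv.forward(x, B, H, W, train);
    y = bn.forward(y, train);
    return relu.forward(y, train);
  }
  mat backward(const mat& gy, double lr, long t) {
    mat g = relu.backward(gy);
    g = bn.backward(g, lr, t);
    return conv.backward(g, lr, t);
  }
};

struct Pool {  // 2x2 max pool, stride 2
  umat idx; int B, H, W, C;
  mat forward(const mat& x, int B_, int H_, int W_, bool keep) {
    B = B_; H = H_; W = W_; C = x.n_cols;
    int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
    mat y(B * HW2, C);
    umat id(B * HW2, C);
    for (int c = 0; c < C; ++c) {
      const double* src = x.colptr(c);
      double* dst = y.colptr(c);
      uword* ic = id.colptr(c);
      for (int b = 0; b < B; ++b)
        for (int w = 0; w < W2; ++w)
          for (int h = 0; h < H2; ++h) {
            uword best = (size_t)b * HW + (2 * w) * H + 2 * h;
            double bv = src[best];
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                uword k = (size_t)b * HW + (2 * w + j) * H + (2 * h + i);
                if (src[k] > bv) { bv = src[k]; best = k; }
              }
            dst[(size_t)b * HW2 + w * H2 + h] = bv;
            ic[(size_t)b * HW2 + w * H2 + h] = best;
          }
    }
    if (keep) idx = std::move(id);
    return y;
  }
  mat backward(const mat& gy) {
    mat gx(B * H * W, C, fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* g = gy.colptr(c);
      const uword* ic = idx.colptr(c);
      double* dst = gx.colptr(c);
      for (uword r = 0; r < gy.n_rows; ++r) dst[ic[r]] += g[r];
    }
    idx.reset();
    return gx;
  }
};

struct Up {  // nearest-neighbour 2x upsampling
  int B, H, W;
  mat forward(const mat& x, int B_, int H_, int W_) {
    B = B_; H = H_; W = W_;
    int H2 = 2 * H, W2 = 2 * W, HW = H * W, HW2 = H2 * W2, C = x.n_cols;
    mat y(B * HW2, C);
    for (int c = 0; c < C; ++c) {
      const double* src = x.colptr(c);
      double* dst = y.colptr(c);
      for (int b = 0; b < B; ++b)
        for (int w = 0; w < W2; ++w)
          for (int h = 0; h < H2; ++h)
            dst[(size_t)b * HW2 + w * H2 + h] = src[(size_t)b * HW + (w / 2) * H + h / 2];
    }
    return y;
  }
  mat backward(const mat& gy) {
    int H2 = 2 * H, W2 = 2 * W, HW = H * W, HW2 = H2 * W2, C = gy.n_cols;
    mat gx(B * HW, C, fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* g = gy.colptr(c);
      double* dst = gx.colptr(c);
      for (int b = 0; b < B; ++b)
        for (int w = 0; w < W2; ++w)
          for (int h = 0; h < H2; ++h)
            dst[(size_t)b * HW + (w / 2) * H + h / 2] += g[(size_t)b * HW2 + w * H2 + h];
    }
    return gx;
  }
};

struct Drop {
  mat mask;
  mat forward(const mat& x, double p, std::mt19937& rng) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    mask.set_size(x.n_rows, x.n_cols);
    double s = 1.0 / (1.0 - p);
    for (uword i = 0; i < mask.n_elem; ++i) mask(i) = (u(rng) < p) ? 0.0 : s;
    return x % mask;
  }
  mat backward(const mat& gy) { mat gx = gy % mask; mask.reset(); return gx; }
};

class UNet {
public:
  int cin, cout, base, depth, head;  // head: 0 map, 1 class
  double drop_enc;
  vec drop_in;  // per-input-channel dropout (training only)
  std::mt19937 rng;
  long tstep;

  std::vector<ConvBlock> encA, encB, upc, decA, decB;
  ConvBlock botA, botB;
  mat headW; rowvec headB;  // 1x1 conv (map) or dense on pooled features (class)
  Adam aHW, aHB;

  // forward caches
  std::vector<Pool> pools;
  std::vector<Up> ups;
  std::vector<Drop> edrops;
  Drop indrop;
  std::vector<mat> skips;
  mat cacheTop, cachePooled, cacheOut;
  std::vector<int> gskipPending;
  std::vector<mat> gskip;
  int cB, cH, cW;

  UNet(int ci, int co, int base_, int depth_, int head_, double de,
       const vec& di, unsigned seed)
      : cin(ci), cout(co), base(base_), depth(depth_), head(head_),
        drop_enc(de), drop_in(di), rng(seed), tstep(0) {
    encA.resize(depth); encB.resize(depth);
    upc.resize(depth); decA.resize(depth); decB.resize(depth);
    pools.resize(depth); ups.resize(depth); edrops.resize(depth);
    skips.resize(depth); gskip.resize(depth);
    for (int d = 0; d < depth; ++d) {
      int ci_d = (d == 0) ? cin : (base << (d - 1));
      int co_d = base << d;
      encA[d].init(ci_d, co_d, rng);
      encB[d].init(co_d, co_d, rng);
    }
    int cb = base << depth;
    botA.init(base << (depth - 1), cb, rng);
    botB.init(cb, cb, rng);
    for (int d = depth - 1; d >= 0; --d) {
      int ch = base << d;
      upc[d].init(ch * 2, ch, rng);
      decA[d].init(ch * 2, ch, rng);
      decB[d].init(ch, ch, rng);
    }
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / base));
    if (head == 0) { headW.set_size(base, cout); } else { headW.set_size(base, 2); }
    for (uword i = 0; i < headW.n_elem; ++i) headW(i) = nd(rng);
    headB.zeros(headW.n_cols);
    aHW.init(headW);
    mat hb = conv_to<mat>::from(headB); aHB.init(hb);
  }

  // returns map-head sigmoid output (B*H*W x cout) or class-head softmax (B x 2)
  mat forward(const mat& X, int B, int H, int W, bool train) {
    cB = B; cH = H; cW = W;
    mat x = X;
    if (train && any(drop_in > 0)) {
      std::uniform_real_distribution<double> u(0.0, 1.0);
      for (int c = 0; c < cin; ++c) {
        double p = drop_in(c);
        if (p <= 0) continue;
        double s = 1.0 / (1.0 - p);
        double* col = x.colptr(c);
        for (uword r = 0; r < x.n_rows; ++r) col[r] = (u(rng) < p) ? 0.0 : col[r] * s;
      }
    }
    int h = H, w = W;
    for (int d = 0; d < depth; ++d) {
      x = encA[d].forward(x, B, h, w, train);
      x = encB[d].forward(x, B, h, w, train);
      if (train && drop_enc > 0) x = edrops[d].forward(x, drop_enc, rng);
      skips[d] = x;
      x = pools[d].forward(x, B, h, w, train);
      h /= 2; w /= 2;
    }
    x = botA.forward(x, B, h, w, train);
    x = botB.forward(x, B, h, w, train);
    for (int d = depth - 1; d >= 0; --d) {
      x = ups[d].forward(x, B, h, w);
      h *= 2; w *= 2;
      x = upc[d].forward(x, B, h, w, train);
      x = join_rows(skips[d], x);
      x = decA[d].forward(x, B, h, w, train);
      x = decB[d].forward(x, B, h, w, train);
      if (!train) skips[d].reset();
    }
    if (head == 0) {
      mat z = x * headW;
      z.each_row() += headB;
      if (train) cacheTop = std::move(x);
      mat o = 1.0 / (1.0 + exp(-z));
      if (train) cacheOut = o;
      return o;
    }
    // class head: global average pool per sample, dense, softmax
    int HW = H * W;
    mat P(B, base);
    for (int b = 0; b < B; ++b) P.row(b) = mean(x.rows((size_t)b * HW, (size_t)(b + 1) * HW - 1), 0);
    if (train) { cacheTop = std::move(x); cachePooled = P; }
    mat z = P * headW;
    z.each_row() += headB;
    z.each_col() -= max(z, 1);
    mat e = exp(z);
    mat o = e.each_col() / sum(e, 1);
    if (train) cacheOut = o;
    return o;
  }

  // cross-entropy on the cached training forward; backward + Adam update
  double train_step(const mat& t, double lr) {
    ++tstep;
    mat o = clamp(cacheOut, CE_EPS, 1.0 - CE_EPS);
    double n = (double)o.n_elem;
    double loss = accu(-(t % log(o) + (1.0 - t) % log(1.0 - o))) / n;
    mat gz;
    if (head == 0) {
      gz = (cacheOut - t) / n;  // sigmoid + per-entry CE
    } else {
      mat go = (-(t / o) + (1.0 - t) / (1.0 - o)) / n;
      // softmax jacobian: gz_k = o_k * (go_k - sum_j go_j o_j)
      vec dot = sum(go % cacheOut, 1);
      gz = cacheOut % (go.each_col() - dot);
    }
    cacheOut.reset();
    mat gW, gx;
    if (head == 0) {
      gW = cacheTop.t() * gz;
      gx = gz * headW.t();
    } else {
      gW = cachePooled.t() * gz;
      mat gP = gz * headW.t();
      int HW = cH * cW;
      int hb = cH >> depth, wb = cW >> depth;  // not used; keep full res
      gx.set_size((size_t)cB * HW, base);
      for (int b = 0; b < cB; ++b)
        gx.rows((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
            repmat(gP.row(b) / (double)HW, HW, 1);
      (void)hb; (void)wb;
    }
    rowvec gb = sum(gz, 0);
    cacheTop.reset(); cachePooled.reset();
    aHW.step(headW, gW, lr, tstep);
    mat hb2 = conv_to<mat>::from(headB), gb2 = conv_to<mat>::from(gb);
    aHB.step(hb2, gb2, lr, tstep);
    headB = hb2.row(0);

    int h = cH >> depth, w = cW >> depth;
    for (int d = 0; d < depth; ++d) {
      gx = decB[d].backward(gx, lr, tstep);
      gx = decA[d].backward(gx, lr, tstep);
      int ch = base << d;
      gskip[d] = gx.cols(0, ch - 1);
      gx = upc[d].backward(gx.cols(ch, 2 * ch - 1).eval(), lr, tstep);
      gx = ups[d].backward(gx);
    }
    gx = botB.backward(gx, lr, tstep);
    gx = botA.backward(gx, lr, tstep);
    for (int d = depth - 1; d >= 0; --d) {
      gx = pools[d].backward(gx);
      gx += gskip[d];
      gskip[d].reset(); skips[d].reset();
      if (drop_enc > 0) gx = edrops[d].backward(gx);
      gx = encB[d].backward(gx, lr, tstep);
      gx = encA[d].backward(gx, lr, tstep);
    }
    return loss;
  }

  List state() {
    List out;
    std::vector<ConvBlock*> blocks = allBlocks();
    for (size_t i = 0; i < blocks.size(); ++i) {
      ConvBlock* cb = blocks[i];
      out.push_back(Rcpp::wrap(cb->conv.W));
      out.push_back(Rcpp::wrap(conv_to<mat>::from(cb->conv.b)));
      out.push_back(Rcpp::wrap(conv_to<mat>::from(cb->bn.g)));
      out.push_back(Rcpp::wrap(conv_to<mat>::from(cb->bn.beta)));
      out.push_back(Rcpp::wrap(conv_to<mat>::from(cb->bn.rmean)));
      out.push_back(Rcpp::wrap(conv_to<mat>::from(cb->bn.rvar)));
    }
    out.push_back(Rcpp::wrap(headW));
    out.push_back(Rcpp::wrap(conv_to<mat>::from(headB)));
    return out;
  }

  void setState(List st) {
    std::vector<ConvBlock*> blocks = allBlocks();
    int k = 0;
    for (size_t i = 0; i < blocks.size(); ++i) {
      ConvBlock* cb = blocks[i];
      cb->conv.W = Rcpp::as<mat>(st[k++]);
      cb->conv.b = Rcpp::as<mat>(st[k++]).row(0);
      cb->bn.g = Rcpp::as<mat>(st[k++]).row(0);
      cb->bn.beta = Rcpp::as<mat>(st[k++]).row(0);
      cb->bn.rmean = Rcpp::as<mat>(st[k++]).row(0);
      cb->bn.rvar = Rcpp::as<mat>(st[k++]).row(0);
    }
    headW = Rcpp::as<mat>(st[k++]);
    headB = Rcpp::as<mat>(st[k++]).row(0);
  }

  double nparams() {
    double n = 0;
    std::vector<ConvBlock*> blocks = allBlocks();
    for (size_t i = 0; i < blocks.size(); ++i)
      n += blocks[i]->conv.W.n_elem + blocks[i]->conv.b.n_elem +
           2.0 * blocks[i]->bn.g.n_elem;
    return n + headW.n_elem + headB.n_elem;
  }

private:
  std::vector<ConvBlock*> allBlocks() {
    std::vector<ConvBlock*> v;
    for (int d = 0; d < depth; ++d) { v.push_back(&encA[d]); v.push_back(&encB[d]); }
    v.push_back(&botA); v.push_back(&botB);
    for (int d = depth - 1; d >= 0; --d) {
      v.push_back(&upc[d]); v.push_back(&decA[d]); v.push_back(&decB[d]);
    }
    return v;
  }
};

static mat arr_to_mat(const Rcpp::NumericVector& a, int H, int W, int C, int B) {
  size_t HW = (size_t)H * W;
  mat X((size_t)B * HW, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      std::memcpy(X.colptr(c) + (size_t)b * HW, a.begin() + HW * ((size_t)b * C + c),
                  HW * sizeof(double));
  return X;
}

static Rcpp::NumericVector mat_to_arr(const mat& Y, int H, int W, int B) {
  int C = Y.n_cols;
  size_t HW = (size_t)H * W;
  Rcpp::NumericVector a(HW * C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      std::memcpy(a.begin() + HW * ((size_t)b * C + c), Y.colptr(c) + (size_t)b * HW,
                  HW * sizeof(double));
  a.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  return a;
}

// [[Rcpp::export]]
SEXP cpp_unet_create(int cin, int cout, int base, int depth, int head,
                     double drop_enc, Rcpp::NumericVector drop_in, int seed) {
  vec di(cin, fill::zeros);
  for (int i = 0; i < std::min((int)drop_in.size(), cin); ++i) di(i) = drop_in[i];
  XPtr<UNet> p(new UNet(cin, cout, base, depth, head, drop_enc, di,
                        (unsigned)seed), true);
  return p;
}

// [[Rcpp::export]]
SEXP cpp_unet_forward(SEXP ptr, Rcpp::NumericVector x) {
  XPtr<UNet> net(ptr);
  Rcpp::IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  mat X = arr_to_mat(x, H, W, C, B);
  mat o = net->forward(X, B, H, W, false);
  if (net->head == 0) return mat_to_arr(o, H, W, B);
  return Rcpp::wrap(o);
}

// [[Rcpp::export]]
double cpp_unet_train_batch(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector t,
                            double lr) {
  XPtr<UNet> net(ptr);
  Rcpp::IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  mat X = arr_to_mat(x, H, W, C, B);
  net->forward(X, B, H, W, true);
  mat T;
  if (net->head == 0) {
    Rcpp::IntegerVector dt = t.attr("dim");
    T = arr_to_mat(t, dt[0], dt[1], dt[2], dt[3]);
  } else {
    T = Rcpp::as<mat>(t);
  }
  return net->train_step(T, lr);
}

// [[Rcpp::export]]
double cpp_unet_eval_loss(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector t) {
  XPtr<UNet> net(ptr);
  Rcpp::IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  mat X = arr_to_mat(x, H, W, C, B);
  mat o = net->forward(X, B, H, W, false);
  mat T;
  if (net->head == 0) {
    Rcpp::IntegerVector dt = t.attr("dim");
    T = arr_to_mat(t, dt[0], dt[1], dt[2], dt[3]);
  } else {
    T = Rcpp::as<mat>(t);
  }
  mat oc = clamp(o, CE_EPS, 1.0 - CE_EPS);
  return accu(-(T % log(oc) + (1.0 - T) % log(1.0 - oc))) / (double)o.n_elem;
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP ptr) { return XPtr<UNet>(ptr)->nparams(); }

// [[Rcpp::export]]
List cpp_unet_state(SEXP ptr) { return XPtr<UNet>(ptr)->state(); }

// [[Rcpp::export]]
void cpp_unet_set_state(SEXP ptr, List st) { XPtr<UNet>(ptr)->setState(st); }
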