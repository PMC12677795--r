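// CPU engine for the five-level encoder-decoder segmentation network.
// Images are arma::cube (H x W x C); a batch is a vector of cubes.
// Convolutions are 'same'-padded 3x3 (head 1x1) via im2col + GEMM; the
// im2col matrices are recomputed in the backward pass rather than cached,
// trading ~30% compute for a much smaller memory footprint. Transpose
// convolutions are 2x2 stride 2. Batch norm uses population batch
// statistics with running-average updates (momentum 0.1, eps 1e-5).
// All randomness (init, shuffling) lives on the R side; this engine is
// deterministic.

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

typedef std::vector<arma::cube> Batch;

static const double BN_EPS = 1e-5;

// ---- low-level layers -----------------------------------------------------

// column index j*H + i holds the receptive field of output pixel (i, j);
// row index c*k*k + kj*k + ki holds input channel c at offset (ki-p, kj-p)
static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int iLo = std::max(0, -di), iHi = std::min(H, H - di);
          for (int i = iLo; i < iHi; ++i)
            cols(r, j * H + i) = xs(i + di, sj);
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube& dx, const mat& dcols, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        const int di = ki - p, dj = kj - p;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int iLo = std::max(0, -di), iHi = std::min(H, H - di);
          for (int i = iLo; i < iHi; ++i)
            xs(i + di, sj) += dcols(r, j * H + i);
        }
      }
    }
  }
}

static cube conv_fwd(const cube& x, const mat& W, const vec& b, int k) {
  const int H = x.n_rows, Wd = x.n_cols, outC = W.n_rows;
  mat Y = W * im2col(x, k);
  Y.each_col() += b;
  cube out(H, Wd, outC);
  mat Yt = Y.t();
  for (int o = 0; o < outC; ++o)
    out.slice(o) = reshape(Yt.col(o), H, Wd);
  return out;
}

static cube conv_bwd(const cube& dy, const cube& x, const mat& W, int k,
                     mat& dW, vec& db) {
  const int H = x.n_rows, Wd = x.n_cols, outC = W.n_rows;
  mat dY(outC, H * Wd);
  for (int o = 0; o < outC; ++o)
    dY.row(o) = vectorise(dy.slice(o)).t();
  mat cols = im2col(x, k);
  dW += dY * cols.t();
  db += sum(dY, 1);
  mat dcols = W.t() * dY;
  cube dx(H, Wd, x.n_slices, fill::zeros);
  col2im_add(dx, dcols, k);
  return dx;
}

static cube pool_fwd(const cube& x, ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  const int H0 = x.n_rows;
  cube y(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double v = xs(bi, bj);
        int best = bj * H0 + bi;
        if (xs(bi + 1, bj) > v) { v = xs(bi + 1, bj); best = bj * H0 + bi + 1; }
        if (xs(bi, bj + 1) > v) { v = xs(bi, bj + 1); best = (bj + 1) * H0 + bi; }
        if (xs(bi + 1, bj + 1) > v) {
          v = xs(bi + 1, bj + 1); best = (bj + 1) * H0 + bi + 1;
        }
        y(i, j, c) = v;
        idx(i, j, c) = best;
      }
    }
  }
  return y;
}

static cube pool_bwd(const cube& dy, const ucube& idx, int H0, int W0) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(H0, W0, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ds = dx.slice(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        ds(idx(i, j, c)) += dy(i, j, c);
  }
  return dx;
}

// weight layout: row o*4 + dj*2 + di maps input pixel (i, j) to output
// pixel (2i+di, 2j+dj) of channel o
static cube tconv_fwd(const cube& x, const mat& Wt, const vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outC = Wt.n_rows / 4;
  mat X(C, H * W);
  for (int c = 0; c < C; ++c)
    X.row(c) = vectorise(x.slice(c)).t();
  mat Y4 = Wt * X;
  cube out(2 * H, 2 * W, outC);
  for (int o = 0; o < outC; ++o) {
    mat& os = out.slice(o);
    os.fill(b(o));
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int r = o * 4 + dj * 2 + di;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            os(2 * i + di, 2 * j + dj) += Y4(r, j * H + i);
      }
    }
  }
  return out;
}

static cube tconv_bwd(const cube& dy, const cube& x, const mat& Wt,
                      mat& dW, vec& db) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outC = Wt.n_rows / 4;
  mat X(C, H * W);
  for (int c = 0; c < C; ++c)
    X.row(c) = vectorise(x.slice(c)).t();
  mat dY4(outC * 4, H * W);
  for (int o = 0; o < outC; ++o) {
    const mat& ds = dy.slice(o);
    db(o) += accu(ds);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int r = o * 4 + dj * 2 + di;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dY4(r, j * H + i) = ds(2 * i + di, 2 * j + dj);
      }
  }
  dW += dY4 * X.t();
  mat dX = Wt.t() * dY4;
  cube dx(H, W, C);
  mat dXt = dX.t();
  for (int c = 0; c < C; ++c)
    dx.slice(c) = reshape(dXt.col(c), H, W);
  return dx;
}

static void relu_inplace(Batch& x) {
  for (auto& c : x) c.transform([](double v) { return v > 0 ? v : 0.0; });
}

static Batch relu_bwd(const Batch& d, const Batch& out) {
  Batch dx(d.size());
  for (size_t b = 0; b < d.size(); ++b)
    dx[b] = d[b] % conv_to<cube>::from(out[b] > 0);
  return dx;
}

struct BNCache {
  Batch xhat;
  vec invstd;
};

static Batch bn_fwd_train(const Batch& x, const vec& g, const vec& be,
                          vec& rm, vec& rv, double momentum, BNCache& cache) {
  const int C = x[0].n_slices, B = x.size();
  const double M = (double)B * x[0].n_rows * x[0].n_cols;
  vec mean(C, fill::zeros), var(C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      mean(c) += accu(x[b].slice(c));
  mean /= M;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      var(c) += accu(square(x[b].slice(c) - mean(c)));
  var /= M;
  cache.invstd = 1.0 / sqrt(var + BN_EPS);
  cache.xhat.resize(B);
  Batch y(B);
  for (int b = 0; b < B; ++b) {
    cache.xhat[b].set_size(size(x[b]));
    y[b].set_size(size(x[b]));
    for (int c = 0; c < C; ++c) {
      cache.xhat[b].slice(c) = (x[b].slice(c) - mean(c)) * cache.invstd(c);
      y[b].slice(c) = g(c) * cache.xhat[b].slice(c) + be(c);
    }
  }
  rm = (1 - momentum) * rm + momentum * mean;
  rv = (1 - momentum) * rv + momentum * var;
  return y;
}

static Batch bn_fwd_eval(const Batch& x, const vec& g, const vec& be,
                         const vec& rm, const vec& rv) {
  const int C = x[0].n_slices, B = x.size();
  Batch y(B);
  vec invstd = 1.0 / sqrt(rv + BN_EPS);
  for (int b = 0; b < B; ++b) {
    y[b].set_size(size(x[b]));
    for (int c = 0; c < C; ++c)
      y[b].slice(c) = g(c) * (x[b].slice(c) - rm(c)) * invstd(c) + be(c);
  }
  return y;
}

static Batch bn_bwd(const Batch& dy, const BNCache& cache, const vec& g,
                    vec& dg, vec& dbe) {
  const int C = dy[0].n_slices, B = dy.size();
  const double M = (double)B * dy[0].n_rows * dy[0].n_cols;
  vec sumDy(C, fill::zeros), sumDyXhat(C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      sumDy(c) += accu(dy[b].slice(c));
      sumDyXhat(c) += accu(dy[b].slice(c) % cache.xhat[b].slice(c));
    }
  dg += sumDyXhat;
  dbe += sumDy;
  Batch dx(B);
  for (int b = 0; b < B; ++b) {
    dx[b].set_size(size(dy[b]));
    for (int c = 0; c < C; ++c)
      dx[b].slice(c) = g(c) * cache.invstd(c) *
        (dy[b].slice(c) - sumDy(c) / M -
         cache.xhat[b].slice(c) * (sumDyXhat(c) / M));
  }
  return dx;
}

// ---- weight/grad bookkeeping ----------------------------------------------

struct Params {
  List w;
  mat M(const std::string& n) const { return as<mat>(w[n]); }
  vec V(const std::string& n) const { return as<vec>(w[n]); }
};

struct Grads {
  std::map<std::string, mat> m;
  std::map<std::string, vec> v;
  mat& M(const std::string& n, const mat& like) {
    if (!m.count(n)) m[n] = mat(like.n_rows, like.n_cols, fill::zeros);
    return m[n];
  }
  vec& V(const std::string& n, size_t len) {
    if (!v.count(n)) v[n] = vec(len, fill::zeros);
    return v[n];
  }
};

static Batch batch_conv(const Batch& x, const mat& W, const vec& b, int k) {
  Batch y(x.size());
  for (size_t i = 0; i < x.size(); ++i) y[i] = conv_fwd(x[i], W, b, k);
  return y;
}

static Batch batch_conv_bwd(const Batch& dy, const Batch& x, const mat& W,
                            int k, mat& dW, vec& db) {
  Batch dx(x.size());
  for (size_t i = 0; i < x.size(); ++i)
    dx[i] = conv_bwd(dy[i], x[i], W, k, dW, db);
  return dx;
}

// ---- full network ----------------------------------------------------------

struct Caches {
  Batch encIn[5], encA1[5], encOut[5];
  BNCache encBN[5];
  std::vector<ucube> poolIdx[5];   // pool feeding block i+1 (0..3) and middle (4)
  Batch midIn, midA1, midOut;
  BNCache midBN;
  Batch decIn[5], decCat[5], decA1[5], decOut[5];
  BNCache decBN[5];
  Batch logits, probs;
};

// forward pass; training mode caches everything and uses batch statistics
typedef std::map<std::string, vec> VecMap;

static void forward(const Params& P, const Batch& x, const IntegerVector& encC,
                    int midC, const IntegerMatrix& plan, bool training,
                    double momentum, Caches& S, VecMap& runningOut) {
  const int B = x.size();
  Batch cur = x;
  char nm[64];
  for (int i = 0; i < 5; ++i) {
    if (i > 0) {
      S.poolIdx[i - 1].resize(B);
      Batch pooled(B);
      for (int b = 0; b < B; ++b)
        pooled[b] = pool_fwd(cur[b], S.poolIdx[i - 1][b]);
      cur = pooled;
    }
    S.encIn[i] = cur;
    snprintf(nm, 64, "enc%d_c1", i + 1);
    cur = batch_conv(cur, P.M(std::string(nm) + "_W"),
                     P.V(std::string(nm) + "_b"), 3);
    relu_inplace(cur);
    S.encA1[i] = cur;
    snprintf(nm, 64, "enc%d_c2", i + 1);
    cur = batch_conv(cur, P.M(std::string(nm) + "_W"),
                     P.V(std::string(nm) + "_b"), 3);
    snprintf(nm, 64, "enc%d_bn", i + 1);
    std::string bn(nm);
    if (training) {
      vec rm = P.V(bn + "_rm"), rv = P.V(bn + "_rv");
      cur = bn_fwd_train(cur, P.V(bn + "_g"), P.V(bn + "_b"), rm, rv,
                         momentum, S.encBN[i]);
      runningOut[bn + "_rm"] = rm;
      runningOut[bn + "_rv"] = rv;
    } else {
      cur = bn_fwd_eval(cur, P.V(bn + "_g"), P.V(bn + "_b"),
                        P.V(bn + "_rm"), P.V(bn + "_rv"));
    }
    relu_inplace(cur);
    S.encOut[i] = cur;
  }

  S.poolIdx[4].resize(B);
  Batch pooled(B);
  for (int b = 0; b < B; ++b)
    pooled[b] = pool_fwd(cur[b], S.poolIdx[4][b]);
  S.midIn = pooled;
  cur = batch_conv(pooled, P.M("mid_c1_W"), P.V("mid_c1_b"), 3);
  relu_inplace(cur);
  S.midA1 = cur;
  cur = batch_conv(cur, P.M("mid_c2_W"), P.V("mid_c2_b"), 3);
  if (training) {
    vec rm = P.V("mid_bn_rm"), rv = P.V("mid_bn_rv");
    cur = bn_fwd_train(cur, P.V("mid_bn_g"), P.V("mid_bn_b"), rm, rv,
                       momentum, S.midBN);
    runningOut["mid_bn_rm"] = rm;
    runningOut["mid_bn_rv"] = rv;
  } else {
    cur = bn_fwd_eval(cur, P.V("mid_bn_g"), P.V("mid_bn_b"),
                      P.V("mid_bn_rm"), P.V("mid_bn_rv"));
  }
  relu_inplace(cur);
  S.midOut = cur;

  for (int j = 0; j < 5; ++j) {
    S.decIn[j] = cur;
    snprintf(nm, 64, "dec%d_up", j + 1);
    Batch up(B);
    {
      mat W = P.M(std::string(nm) + "_W");
      vec b = P.V(std::string(nm) + "_b");
      for (int bb = 0; bb < B; ++bb) up[bb] = tconv_fwd(cur[bb], W, b);
    }
    const Batch& skip = S.encOut[4 - j];
    Batch cat(B);
    for (int bb = 0; bb < B; ++bb)
      cat[bb] = join_slices(up[bb], skip[bb]);
    S.decCat[j] = cat;
    snprintf(nm, 64, "dec%d_c1", j + 1);
    cur = batch_conv(cat, P.M(std::string(nm) + "_W"),
                     P.V(std::string(nm) + "_b"), 3);
    relu_inplace(cur);
    S.decA1[j] = cur;
    snprintf(nm, 64, "dec%d_c2", j + 1);
    cur = batch_conv(cur, P.M(std::string(nm) + "_W"),
                     P.V(std::string(nm) + "_b"), 3);
    snprintf(nm, 64, "dec%d_bn", j + 1);
    std::string bn(nm);
    if (training) {
      vec rm = P.V(bn + "_rm"), rv = P.V(bn + "_rv");
      cur = bn_fwd_train(cur, P.V(bn + "_g"), P.V(bn + "_b"), rm, rv,
                         momentum, S.decBN[j]);
      runningOut[bn + "_rm"] = rm;
      runningOut[bn + "_rv"] = rv;
    } else {
      cur = bn_fwd_eval(cur, P.V(bn + "_g"), P.V(bn + "_b"),
                        P.V(bn + "_rm"), P.V(bn + "_rv"));
    }
    relu_inplace(cur);
    S.decOut[j] = cur;
  }

  S.logits = batch_conv(cur, P.M("head_W"), P.V("head_b"), 1);
  S.probs.resize(B);
  for (int b = 0; b < B; ++b)
    S.probs[b] = 1.0 / (1.0 + exp(-S.logits[b]));
}

static Batch toBatch(const List& xs) {
  Batch out(xs.size());
  for (int i = 0; i < xs.size(); ++i) {
    NumericVector a(xs[i]);
    IntegerVector d = a.attr("dim");
    out[i] = cube(a.begin(), d[0], d[1], d.size() > 2 ? d[2] : 1);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_unet_predict(List weights, List xs, IntegerVector encC, int midC,
                      IntegerMatrix plan, int inC) {
  Params P{weights};
  Batch x = toBatch(xs);
  Caches S;
  VecMap dummy;
  forward(P, x, encC, midC, plan, false, 0.1, S, dummy);
  List out(x.size());
  for (size_t b = 0; b < x.size(); ++b) {
    NumericMatrix m(S.probs[b].n_rows, S.probs[b].n_cols);
    std::copy(S.probs[b].begin(), S.probs[b].end(), m.begin());
    out[b] = m;
  }
  return out;
}

// loss + dLoss/dLogits; masks y are H x W matrices
static double loss_and_grad(const Batch& probs, const std::vector<mat>& ys,
                            const std::string& loss, Batch& dlogits) {
  const int B = probs.size();
  double total = 0;
  dlogits.resize(B);
  const bool doBce = (loss == "bce" || loss == "bce_plus_dice");
  const bool doDice = (loss == "dice" || loss == "bce_plus_dice");
  const double smooth = 1.0;
  for (int b = 0; b < B; ++b) {
    const mat p = probs[b].slice(0);
    const mat& y = ys[b];
    const double n = p.n_elem;
    mat dL(p.n_rows, p.n_cols, fill::zeros);
    if (doBce) {
      mat pc = clamp(p, 1e-7, 1 - 1e-7);
      total += accu(-(y % log(pc) + (1 - y) % log(1 - pc))) / n / B;
      dL += (p - y) / n / B;          // derivative taken on logits directly
    }
    if (doDice) {
      const double sp = accu(p), sy = accu(y), inter = accu(p % y);
      const double den = sp + sy + smooth;
      total += (1.0 - (2 * inter + smooth) / den) / B;
      mat dp = -(2 * y * den - (2 * inter + smooth)) / (den * den) / B;
      dL += dp % p % (1 - p);         // chain through the sigmoid
    }
    dlogits[b] = cube(p.n_rows, p.n_cols, 1);
    dlogits[b].slice(0) = dL;
  }
  return total;
}

// [[Rcpp::export]]
List cpp_unet_train(List weights, List xs, List ys, IntegerVector encC,
                    int midC, IntegerMatrix plan, int inC, std::string loss,
                    double momentum) {
  Params P{weights};
  Batch x = toBatch(xs);
  const int B = x.size();
  std::vector<mat> masks(B);
  for (int b = 0; b < B; ++b) masks[b] = as<mat>(ys[b]);

  Caches S;
  VecMap running;
  forward(P, x, encC, midC, plan, true, momentum, S, running);

  Batch dlogits;
  double lossVal = loss_and_grad(S.probs, masks, loss, dlogits);

  Grads G;
  char nm[64];

  // gradient accumulators for the encoder block outputs (skip + main path)
  Batch dEnc[5];
  for (int i = 0; i < 5; ++i) {
    dEnc[i].resize(B);
    for (int b = 0; b < B; ++b)
      dEnc[i][b] = cube(S.encOut[i][b].n_rows, S.encOut[i][b].n_cols,
                        S.encOut[i][b].n_slices, fill::zeros);
  }

  // head
  mat headW = P.M("head_W");
  Batch d = batch_conv_bwd(dlogits, S.decOut[4], headW, 1,
                           G.M("head_W", headW), G.V("head_b", headW.n_rows));

  // decoder, last block first
  for (int j = 4; j >= 0; --j) {
    d = relu_bwd(d, S.decOut[j]);
    snprintf(nm, 64, "dec%d_bn", j + 1);
    std::string bn(nm);
    vec g = P.V(bn + "_g");
    d = bn_bwd(d, S.decBN[j], g, G.V(bn + "_g", g.n_elem),
               G.V(bn + "_b", g.n_elem));
    snprintf(nm, 64, "dec%d_c2", j + 1);
    {
      mat W = P.M(std::string(nm) + "_W");
      d = batch_conv_bwd(d, S.decA1[j], W, 3,
                         G.M(std::string(nm) + "_W", W),
                         G.V(std::string(nm) + "_b", W.n_rows));
    }
    d = relu_bwd(d, S.decA1[j]);
    snprintf(nm, 64, "dec%d_c1", j + 1);
    {
      mat W = P.M(std::string(nm) + "_W");
      d = batch_conv_bwd(d, S.decCat[j], W, 3,
                         G.M(std::string(nm) + "_W", W),
                         G.V(std::string(nm) + "_b", W.n_rows));
    }
    // split concat gradient: transpose-conv channels first, then the skip
    const int upC = plan(j, 1);
    Batch dUp(B);
    for (int b = 0; b < B; ++b) {
      dUp[b] = d[b].slices(0, upC - 1);
      dEnc[4 - j][b] += d[b].slices(upC, d[b].n_slices - 1);
    }
    snprintf(nm, 64, "dec%d_up", j + 1);
    {
      mat W = P.M(std::string(nm) + "_W");
      Batch dPrev(B);
      mat& dW = G.M(std::string(nm) + "_W", W);
      vec& db = G.V(std::string(nm) + "_b", W.n_rows / 4);
      for (int b = 0; b < B; ++b)
        dPrev[b] = tconv_bwd(dUp[b], S.decIn[j][b], W, dW, db);
      d = dPrev;
    }
  }

  // middle
  d = relu_bwd(d, S.midOut);
  {
    vec g = P.V("mid_bn_g");
    d = bn_bwd(d, S.midBN, g, G.V("mid_bn_g", g.n_elem),
               G.V("mid_bn_b", g.n_elem));
  }
  {
    mat W = P.M("mid_c2_W");
    d = batch_conv_bwd(d, S.midA1, W, 3, G.M("mid_c2_W", W),
                       G.V("mid_c2_b", W.n_rows));
  }
  d = relu_bwd(d, S.midA1);
  {
    mat W = P.M("mid_c1_W");
    d = batch_conv_bwd(d, S.midIn, W, 3, G.M("mid_c1_W", W),
                       G.V("mid_c1_b", W.n_rows));
  }
  for (int b = 0; b < B; ++b)
    dEnc[4][b] += pool_bwd(d[b], S.poolIdx[4][b],
                           S.encOut[4][b].n_rows, S.encOut[4][b].n_cols);

  // encoder, deepest block first
  for (int i = 4; i >= 0; --i) {
    d = relu_bwd(dEnc[i], S.encOut[i]);
    snprintf(nm, 64, "enc%d_bn", i + 1);
    std::string bn(nm);
    vec g = P.V(bn + "_g");
    d = bn_bwd(d, S.encBN[i], g, G.V(bn + "_g", g.n_elem),
               G.V(bn + "_b", g.n_elem));
    snprintf(nm, 64, "enc%d_c2", i + 1);
    {
      mat W = P.M(std::string(nm) + "_W");
      d = batch_conv_bwd(d, S.encA1[i], W, 3,
                         G.M(std::string(nm) + "_W", W),
                         G.V(std::string(nm) + "_b", W.n_rows));
    }
    d = relu_bwd(d, S.encA1[i]);
    snprintf(nm, 64, "enc%d_c1", i + 1);
    {
      mat W = P.M(std::string(nm) + "_W");
      d = batch_conv_bwd(d, S.encIn[i], W, 3,
                         G.M(std::string(nm) + "_W", W),
                         G.V(std::string(nm) + "_b", W.n_rows));
    }
    if (i > 0)
      for (int b = 0; b < B; ++b)
        dEnc[i - 1][b] += pool_bwd(d[b], S.poolIdx[i - 1][b],
                                   S.encOut[i - 1][b].n_rows,
                                   S.encOut[i - 1][b].n_cols);
  }

  // package gradients and running-stat updates as named lists
  List grads(G.m.size() + G.v.size());
  CharacterVector gn(grads.size());
  int gi = 0;
  for (auto& kv : G.m) { gn[gi] = kv.first; grads[gi++] = wrap(kv.second); }
  for (auto& kv : G.v) {
    gn[gi] = kv.first;
    grads[gi++] = NumericVector(kv.second.begin(), kv.second.end());
  }
  grads.attr("names") = gn;
  List run(running.size());
  CharacterVector rn(run.size());
  int ri = 0;
  for (auto& kv : running) {
    rn[ri] = kv.first;
    run[ri++] = NumericVector(kv.second.begin(), kv.second.end());
  }
  run.attr("names") = rn;
  return List::create(_["loss"] = lossVal, _["grads"] = grads,
                      _["running"] = run);
}
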