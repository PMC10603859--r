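// Two-channel U-Net with batch normalization, trained with a weighted sum of
// soft Dice losses (MAB, LIB, CVW = MAB - LIB). Convolutions run as
// im2col + GEMM in a transposed layout (columns contiguous in the pixel
// index) so that building/scattering patch matrices is memcpy-bound.
// Single-threaded and deterministic given the parameter initialization.
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

typedef std::map<std::string, mat> ParamMap;

static ParamMap list_to_map(List lst) {
  ParamMap out;
  CharacterVector nm = lst.names();
  for (int i = 0; i < lst.size(); ++i) {
    NumericMatrix m = as<NumericMatrix>(lst[i]);
    out[as<std::string>(nm[i])] = mat(m.begin(), m.nrow(), m.ncol());
  }
  return out;
}

static List map_to_list(const ParamMap &pm) {
  List out;
  CharacterVector nm(pm.size());
  int i = 0;
  for (auto &kv : pm) {
    nm[i] = kv.first;
    out.push_back(wrap(kv.second));
    ++i;
  }
  out.names() = nm;
  return out;
}

// colsT: (H*W, 9*C); column c*9 + kj*3 + ki holds the input shifted by
// (ki-1, kj-1) in channel c, zero-padded
static void im2colT(const cube &A, mat &out) {
  int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  out.set_size((size_t)H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double *src = A.slice_memptr(c);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        double *dst = out.colptr(c * 9 + kj * 3 + ki);
        int dj = kj - 1, di = ki - 1;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          double *d = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) { std::fill(d, d + H, 0.0); continue; }
          const double *s = src + (size_t)sj * H;
          if (i0 > 0) std::fill(d, d + i0, 0.0);
          std::copy(s + i0 + di, s + i1 + di, d + i0);
          if (i1 < H) std::fill(d + i1, d + H, 0.0);
        }
      }
  }
}

// accumulate the transposed patch-gradient matrix back onto the image grid
static void col2imT(const mat &colsT, cube &dA) {
  int H = dA.n_rows, W = dA.n_cols, C = dA.n_slices;
  for (int c = 0; c < C; ++c) {
    double *dst = dA.slice_memptr(c);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const double *src = colsT.colptr(c * 9 + kj * 3 + ki);
        int dj = kj - 1, di = ki - 1;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double *s = src + (size_t)j * H;
          double *d = dst + (size_t)sj * H + di;
          for (int i = i0; i < i1; ++i) d[i] += s[i];
        }
      }
  }
}

// flat (H*W, C) view of a cube's memory (no copy on construction)
static mat flat_view(cube &A) {
  return mat(A.memptr(), (size_t)A.n_rows * A.n_cols, A.n_slices, false);
}

struct BNCache {
  std::vector<cube> xhat;
  vec inv_std;
  vec gamma;
};

struct ConvCache {
  std::vector<cube> input; // conv inputs (im2col recomputed in backward)
};

static void bn_forward(std::vector<cube> &X, ParamMap &P,
                       const std::string &name, bool training, BNCache *cache,
                       double momentum = 0.1, double eps = 1e-5) {
  int B = X.size();
  int C = X[0].n_slices;
  double N = (double)B * X[0].n_rows * X[0].n_cols;
  vec mu(C), var_(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int b = 0; b < B; ++b) s += arma::accu(X[b].slice(c));
      mu[c] = s / N;
      double v = 0;
      for (int b = 0; b < B; ++b)
        v += arma::accu(arma::square(X[b].slice(c) - mu[c]));
      var_[c] = v / N;
    }
    P[name + "_rm"] = (1 - momentum) * P[name + "_rm"] + momentum * mu.t();
    P[name + "_rv"] = (1 - momentum) * P[name + "_rv"] + momentum * var_.t();
  } else {
    mu = P[name + "_rm"].row(0).t();
    var_ = P[name + "_rv"].row(0).t();
  }
  vec gamma = P[name + "_g"].row(0).t();
  vec beta = P[name + "_b"].row(0).t();
  vec inv_std = 1.0 / arma::sqrt(var_ + eps);
  if (cache) {
    cache->xhat.resize(B);
    cache->inv_std = inv_std;
    cache->gamma = gamma;
  }
  for (int b = 0; b < B; ++b) {
    if (cache) cache->xhat[b].set_size(X[b].n_rows, X[b].n_cols, C);
    for (int c = 0; c < C; ++c) {
      mat xh = (X[b].slice(c) - mu[c]) * inv_std[c];
      if (cache) cache->xhat[b].slice(c) = xh;
      X[b].slice(c) = gamma[c] * xh + beta[c];
    }
  }
}

static void bn_backward(std::vector<cube> &dY, const BNCache &cache,
                        ParamMap &G, const std::string &name) {
  int B = dY.size();
  int C = dY[0].n_slices;
  double N = (double)B * dY[0].n_rows * dY[0].n_cols;
  vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      dgamma[c] += arma::accu(dY[b].slice(c) % cache.xhat[b].slice(c));
      dbeta[c] += arma::accu(dY[b].slice(c));
    }
  G[name + "_g"] = dgamma.t();
  G[name + "_b"] = dbeta.t();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      dY[b].slice(c) = (cache.gamma[c] * cache.inv_std[c] / N) *
        (N * dY[b].slice(c) - dbeta[c] -
         cache.xhat[b].slice(c) * dgamma[c]);
}

static void relu_forward(std::vector<cube> &X) {
  for (auto &x : X) x.transform([](double v) { return v > 0 ? v : 0.0; });
}

static void relu_backward(std::vector<cube> &dY, const std::vector<cube> &Y) {
  for (size_t b = 0; b < dY.size(); ++b) {
    const double *y = Y[b].memptr();
    double *d = dY[b].memptr();
    size_t n = dY[b].n_elem;
    for (size_t i = 0; i < n; ++i)
      if (y[i] <= 0) d[i] = 0;
  }
}

static void conv_forward(std::vector<cube> &X, ParamMap &P,
                         const std::string &name, ConvCache *cache) {
  const mat &W = P.at(name + "_W"); // (Cout, 9*Cin)
  int B = X.size();
  if (cache) cache->input.resize(B);
  mat colsT;
  for (int b = 0; b < B; ++b) {
    if (cache) cache->input[b] = X[b];
    im2colT(X[b], colsT);
    int H = X[b].n_rows, Wd = X[b].n_cols;
    mat Yt = colsT * W.t(); // (H*W, Cout)
    X[b] = cube(Yt.memptr(), H, Wd, W.n_rows);
  }
}

static void conv_backward(std::vector<cube> &dY, ConvCache &cache,
                          ParamMap &P, ParamMap &G, const std::string &name) {
  const mat &W = P.at(name + "_W");
  mat dWt(W.n_cols, W.n_rows, arma::fill::zeros);
  int B = dY.size();
  mat colsT;
  for (int b = 0; b < B; ++b) {
    cube &in = cache.input[b];
    im2colT(in, colsT);
    mat dYt = flat_view(dY[b]); // (H*W, Cout)
    dWt += colsT.t() * dYt;
    mat dcolsT = dYt * W; // (H*W, 9*Cin)
    cube dx(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
    col2imT(dcolsT, dx);
    dY[b] = dx;
  }
  G[name + "_W"] = dWt.t();
}

static void pool_forward(std::vector<cube> &X,
                         std::vector<arma::ucube> *idx) {
  int B = X.size();
  if (idx) idx->resize(B);
  for (int b = 0; b < B; ++b) {
    int H = X[b].n_rows, W = X[b].n_cols, C = X[b].n_slices;
    cube out(H / 2, W / 2, C);
    arma::ucube ic(H / 2, W / 2, C);
    for (int c = 0; c < C; ++c) {
      const double *src = X[b].slice_memptr(c);
      for (int j = 0; j < W / 2; ++j)
        for (int i = 0; i < H / 2; ++i) {
          int bi = 2 * i, bj = 2 * j;
          double best = src[bi + (size_t)bj * H];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = src[2 * i + di + (size_t)(2 * j + dj) * H];
              if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
            }
          out(i, j, c) = best;
          ic(i, j, c) = bi + (size_t)bj * H;
        }
    }
    X[b] = out;
    if (idx) (*idx)[b] = ic;
  }
}

static void pool_backward(std::vector<cube> &dY,
                          const std::vector<arma::ucube> &idx, int H, int W) {
  int B = dY.size();
  for (int b = 0; b < B; ++b) {
    int C = dY[b].n_slices;
    cube out(H, W, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      double *dst = out.slice_memptr(c);
      for (arma::uword j = 0; j < dY[b].n_cols; ++j)
        for (arma::uword i = 0; i < dY[b].n_rows; ++i)
          dst[idx[b](i, j, c)] += dY[b](i, j, c);
    }
    dY[b] = out;
  }
}

// transposed conv 2x2 stride 2; weight (4*Cout, Cin), bias (1, Cout)
static void upconv_forward(std::vector<cube> &X, ParamMap &P,
                           const std::string &name,
                           std::vector<cube> *cache_in) {
  const mat &W = P.at(name + "_W");
  const mat &bias = P.at(name + "_b");
  int B = X.size();
  int Cout = W.n_rows / 4;
  if (cache_in) cache_in->resize(B);
  for (int b = 0; b < B; ++b) {
    int H = X[b].n_rows, Wd = X[b].n_cols;
    if (cache_in) (*cache_in)[b] = X[b];
    mat xinT = flat_view(X[b]);      // (H*W, Cin)
    mat patchT = xinT * W.t();       // (H*W, 4*Cout)
    cube out(2 * H, 2 * Wd, Cout);
    for (int c = 0; c < Cout; ++c) {
      double *dst = out.slice_memptr(c);
      for (int q = 0; q < 4; ++q) {
        const double *src = patchT.colptr(4 * c + q);
        int oi = q % 2, oj = q / 2;
        for (int j = 0; j < Wd; ++j) {
          const double *s = src + (size_t)j * H;
          double *d = dst + (size_t)(2 * j + oj) * 2 * H + oi;
          for (int i = 0; i < H; ++i) d[2 * i] = s[i];
        }
      }
      out.slice(c) += bias(0, c);
    }
    X[b] = out;
  }
}

static void upconv_backward(std::vector<cube> &dY,
                            const std::vector<cube> &cache_in, ParamMap &P,
                            ParamMap &G, const std::string &name) {
  const mat &W = P.at(name + "_W");
  int B = dY.size();
  int Cout = W.n_rows / 4, Cin = W.n_cols;
  mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  mat db(1, Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    int H2 = dY[b].n_rows, W2 = dY[b].n_cols;
    int H = H2 / 2, Wd = W2 / 2;
    mat dpatchT((size_t)H * Wd, 4 * Cout);
    for (int c = 0; c < Cout; ++c) {
      db(0, c) += arma::accu(dY[b].slice(c));
      const double *src = dY[b].slice_memptr(c);
      for (int q = 0; q < 4; ++q) {
        double *dst = dpatchT.colptr(4 * c + q);
        int oi = q % 2, oj = q / 2;
        for (int j = 0; j < Wd; ++j) {
          double *d = dst + (size_t)j * H;
          const double *s = src + (size_t)(2 * j + oj) * 2 * H + oi;
          for (int i = 0; i < H; ++i) d[i] = s[2 * i];
        }
      }
    }
    cube incopy = cache_in[b];
    mat xinT = flat_view(incopy);
    dW += (xinT.t() * dpatchT).t();
    mat dxT = dpatchT * W; // (H*W, Cin)
    dY[b] = cube(dxT.memptr(), H, Wd, Cin);
  }
  G[name + "_W"] = dW;
  G[name + "_b"] = db;
}

struct BlockCache {
  ConvCache c1, c2;
  BNCache b1, b2;
  std::vector<cube> r1, r2; // post-ReLU activations
};

// conv-BN-ReLU x2
static void block_forward(std::vector<cube> &X, ParamMap &P,
                          const std::string &base, bool training,
                          BlockCache *cache) {
  conv_forward(X, P, base + "_c1", cache ? &cache->c1 : nullptr);
  bn_forward(X, P, base + "_n1", training, cache ? &cache->b1 : nullptr);
  relu_forward(X);
  if (cache) cache->r1 = X;
  conv_forward(X, P, base + "_c2", cache ? &cache->c2 : nullptr);
  bn_forward(X, P, base + "_n2", training, cache ? &cache->b2 : nullptr);
  relu_forward(X);
  if (cache) cache->r2 = X;
}

static void block_backward(std::vector<cube> &dY, BlockCache &cache,
                           ParamMap &P, ParamMap &G, const std::string &base) {
  relu_backward(dY, cache.r2);
  bn_backward(dY, cache.b2, G, base + "_n2");
  conv_backward(dY, cache.c2, P, G, base + "_c2");
  relu_backward(dY, cache.r1);
  bn_backward(dY, cache.b1, G, base + "_n1");
  conv_backward(dY, cache.c1, P, G, base + "_c1");
}

struct NetCaches {
  std::vector<BlockCache> enc;
  std::vector<std::vector<arma::ucube>> pool_idx;
  std::vector<std::pair<int, int>> pool_dims;
  BlockCache bottleneck;
  std::vector<std::vector<cube>> up_in;
  std::vector<BlockCache> dec;
  std::vector<std::vector<cube>> skips;
  std::vector<cube> out_in; // input to the 1x1 output conv
  std::vector<cube> probs;
};

static std::vector<cube> net_forward(std::vector<cube> X, ParamMap &P,
                                     int depth, bool training,
                                     NetCaches *cc) {
  int B = X.size();
  if (cc) {
    cc->enc.resize(depth);
    cc->pool_idx.resize(depth);
    cc->pool_dims.resize(depth);
    cc->dec.resize(depth);
    cc->up_in.resize(depth);
    cc->skips.resize(depth);
  }
  std::vector<std::vector<cube>> skips(depth);
  char buf[32];
  for (int l = 0; l < depth; ++l) {
    snprintf(buf, sizeof(buf), "enc%d", l + 1);
    block_forward(X, P, buf, training, cc ? &cc->enc[l] : nullptr);
    skips[l] = X;
    if (cc) {
      cc->skips[l] = X;
      cc->pool_dims[l] = {(int)X[0].n_rows, (int)X[0].n_cols};
    }
    pool_forward(X, cc ? &cc->pool_idx[l] : nullptr);
  }
  block_forward(X, P, "bott", training, cc ? &cc->bottleneck : nullptr);
  for (int l = depth - 1; l >= 0; --l) {
    snprintf(buf, sizeof(buf), "up%d", l + 1);
    upconv_forward(X, P, buf, cc ? &cc->up_in[l] : nullptr);
    for (int b = 0; b < B; ++b)
      X[b] = arma::join_slices(skips[l][b], X[b]); // concat [skip, up]
    snprintf(buf, sizeof(buf), "dec%d", l + 1);
    block_forward(X, P, buf, training, cc ? &cc->dec[l] : nullptr);
  }
  const mat &Wo = P.at("out_W"); // (2, C1)
  const mat &bo = P.at("out_b");
  std::vector<cube> probs(B);
  if (cc) cc->out_in.resize(B);
  for (int b = 0; b < B; ++b) {
    if (cc) cc->out_in[b] = X[b];
    int H = X[b].n_rows, Wd = X[b].n_cols;
    mat xinT = flat_view(X[b]);
    mat zT = xinT * Wo.t(); // (H*W, 2)
    zT.each_row() += bo.row(0);
    mat pT = 1.0 / (1.0 + arma::exp(-zT));
    probs[b] = cube(pT.memptr(), H, Wd, 2);
  }
  if (cc) cc->probs = probs;
  return probs;
}

// soft Dice loss and gradient wrt the probability map
static double dice_loss(const mat &y, const mat &p, mat *dp) {
  double eps = 1e-6;
  double inter = arma::accu(y % p);
  double denom = arma::accu(y) + arma::accu(p) + eps;
  double loss = 1.0 - 2.0 * inter / denom;
  if (dp) *dp = -2.0 * (y * denom - inter) / (denom * denom);
  return loss;
}

// [[Rcpp::export]]
List cpp_unet_forward(List params, int depth, List images) {
  ParamMap P = list_to_map(params);
  int B = images.size();
  std::vector<cube> X(B);
  for (int b = 0; b < B; ++b) {
    NumericMatrix img = as<NumericMatrix>(images[b]);
    X[b] = cube(img.begin(), img.nrow(), img.ncol(), 1);
  }
  std::vector<cube> probs = net_forward(X, P, depth, false, nullptr);
  List out(B);
  for (int b = 0; b < B; ++b) {
    NumericVector a(probs[b].begin(), probs[b].end());
    a.attr("dim") = IntegerVector::create(probs[b].n_rows, probs[b].n_cols,
                                          probs[b].n_slices);
    out[b] = a;
  }
  return out;
}

// One optimization step (forward, ATDL-weighted Dice losses, backward, Adam).
// labels: list of H x W x 2 arrays (MAB, LIB). Returns updated params/adam
// state and the unweighted component losses.
// [[Rcpp::export]]
List cpp_unet_train_step(List params, List adam_m, List adam_v, int depth,
                         List images, List labels, NumericVector abc,
                         double lr, int t, double beta1 = 0.9,
                         double beta2 = 0.999, double adam_eps = 1e-8) {
  ParamMap P = list_to_map(params);
  ParamMap M = list_to_map(adam_m);
  ParamMap V = list_to_map(adam_v);
  int B = images.size();
  std::vector<cube> X(B), Y(B);
  for (int b = 0; b < B; ++b) {
    NumericMatrix img = as<NumericMatrix>(images[b]);
    X[b] = cube(img.begin(), img.nrow(), img.ncol(), 1);
    NumericVector lab = as<NumericVector>(labels[b]);
    IntegerVector d = lab.attr("dim");
    Y[b] = cube(lab.begin(), d[0], d[1], d[2]);
  }
  NetCaches cc;
  std::vector<cube> probs = net_forward(X, P, depth, true, &cc);
  double Lm = 0, Ll = 0, Lc = 0;
  std::vector<cube> dP(B);
  for (int b = 0; b < B; ++b) {
    const mat &pm = probs[b].slice(0);
    const mat &pl = probs[b].slice(1);
    mat ym = Y[b].slice(0), yl = Y[b].slice(1);
    mat ycvw = ym - yl;
    mat pcvw = pm - pl;
    // subgradient at exact ties flows through (common at initialization
    // where ReLU-dead pixels give identical channel logits)
    mat active = arma::conv_to<mat>::from(pcvw >= 0);
    pcvw %= active;
    mat dm, dl, dc;
    Lm += dice_loss(ym, pm, &dm);
    Ll += dice_loss(yl, pl, &dl);
    Lc += dice_loss(ycvw, pcvw, &dc);
    dc %= active;
    cube g(pm.n_rows, pm.n_cols, 2);
    g.slice(0) = (abc[0] * dm + abc[2] * dc) / B;
    g.slice(1) = (abc[1] * dl - abc[2] * dc) / B;
    dP[b] = g;
  }
  Lm /= B; Ll /= B; Lc /= B;
  // backward through sigmoid + 1x1 output conv
  ParamMap G;
  const mat &Wo = P.at("out_W");
  mat dWo(Wo.n_rows, Wo.n_cols, arma::fill::zeros);
  mat dbo(1, Wo.n_rows, arma::fill::zeros);
  std::vector<cube> dX(B);
  for (int b = 0; b < B; ++b) {
    int H = dP[b].n_rows, Wd = dP[b].n_cols;
    mat dpT = flat_view(dP[b]);       // (H*W, 2)
    mat pT = flat_view(cc.probs[b]);
    mat dzT = dpT % pT % (1.0 - pT);
    mat xinT = flat_view(cc.out_in[b]);
    dWo += (xinT.t() * dzT).t();
    dbo += arma::sum(dzT, 0);
    mat dxT = dzT * Wo; // (H*W, C1)
    dX[b] = cube(dxT.memptr(), H, Wd, Wo.n_cols);
  }
  G["out_W"] = dWo;
  G["out_b"] = dbo;
  char buf[32];
  // decoder backward: forward ran levels depth..1 (deepest first), so walk
  // levels 1..depth here, carrying the gradient toward the bottleneck and
  // stashing each skip-connection gradient for the encoder pass
  std::vector<std::vector<cube>> dSkip(depth);
  for (int l = 0; l < depth; ++l) {
    snprintf(buf, sizeof(buf), "dec%d", l + 1);
    block_backward(dX, cc.dec[l], P, G, buf);
    int Cs = cc.skips[l][0].n_slices;
    std::vector<cube> dUp(B);
    dSkip[l].resize(B);
    for (int b = 0; b < B; ++b) {
      dSkip[l][b] = dX[b].slices(0, Cs - 1);
      dUp[b] = dX[b].slices(Cs, dX[b].n_slices - 1);
    }
    snprintf(buf, sizeof(buf), "up%d", l + 1);
    upconv_backward(dUp, cc.up_in[l], P, G, buf);
    dX = dUp;
  }
  block_backward(dX, cc.bottleneck, P, G, "bott");
  // encoder backward: deepest level first, back up to the input
  for (int l = depth - 1; l >= 0; --l) {
    pool_backward(dX, cc.pool_idx[l], cc.pool_dims[l].first,
                  cc.pool_dims[l].second);
    for (int b = 0; b < B; ++b) dX[b] += dSkip[l][b];
    snprintf(buf, sizeof(buf), "enc%d", l + 1);
    block_backward(dX, cc.enc[l], P, G, buf);
  }
  // Adam update
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  for (auto &kv : G) {
    mat &m = M[kv.first];
    mat &v = V[kv.first];
    m = beta1 * m + (1 - beta1) * kv.second;
    v = beta2 * v + (1 - beta2) * arma::square(kv.second);
    P[kv.first] -= lr * (m / bc1) / (arma::sqrt(v / bc2) + adam_eps);
  }
  return List::create(_["params"] = map_to_list(P),
                      _["adam_m"] = map_to_list(M),
                      _["adam_v"] = map_to_list(V),
                      _["loss_mab"] = Lm, _["loss_lib"] = Ll,
                      _["loss_cvw"] = Lc);
}
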