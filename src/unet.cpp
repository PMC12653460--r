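// UNet-like encoder-decoder for polar OCT pixel classification.
// Forward pass, cross-entropy + soft-Dice loss, and full backward pass,
// implemented with im2col + GEMM. Layout: feature maps are arma::cube
// (H x W x C); conv weights are (k*k*Cin) x Cout matrices with column
// ordering q = (c*k + ky)*k + kx. A cube's memory is identical to the
// (H*W) x C matrix of its vectorised slices, which the converters exploit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C);
  mat pad(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    pad.zeros();
    pad.submat(1, 1, H, W) = x.slice(c);
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        uword q = (c * 3 + ky) * 3 + kx;
        double* dst = out.colptr(q);
        for (uword j = 0; j < W; ++j) {
          const double* src = pad.colptr(kx + j) + ky;
          std::memcpy(dst + j * H, src, H * sizeof(double));
        }
      }
  }
  return out;
}

static cube col2im3(const mat& g, uword H, uword W, uword C) {
  cube out(H, W, C);
  mat pad(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    pad.zeros();
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        uword q = (c * 3 + ky) * 3 + kx;
        const double* src = g.colptr(q);
        for (uword j = 0; j < W; ++j) {
          double* dst = pad.colptr(kx + j) + ky;
          const double* s = src + j * H;
          for (uword i = 0; i < H; ++i) dst[i] += s[i];
        }
      }
    out.slice(c) = pad.submat(1, 1, H, W);
  }
  return out;
}

static cube mat2cube(const mat& m, uword H, uword W) {
  cube out(H, W, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), m.n_elem * sizeof(double));
  return out;
}

static mat cube2mat(const cube& x) {
  mat out(x.n_rows * x.n_cols, x.n_slices);
  std::memcpy(out.memptr(), x.memptr(), x.n_elem * sizeof(double));
  return out;
}

// cache for one 3x3 conv layer: im2col input and the ReLU activity mask
struct ConvCache {
  mat xcol;
  umat act;           // pre-activation > 0
  uword H = 0, W = 0, Cin = 0;
};

static cube conv3(const cube& x, const mat& Wt, const vec& b, bool relu,
                  ConvCache* cache) {
  mat xcol = im2col3(x);
  mat y = xcol * Wt;
  y.each_row() += b.t();
  if (relu) {
    if (cache) cache->act = y > 0.0;
    y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  if (cache) {
    cache->xcol = std::move(xcol);
    cache->H = x.n_rows; cache->W = x.n_cols; cache->Cin = x.n_slices;
  }
  return mat2cube(y, x.n_rows, x.n_cols);
}

// backward through ReLU + conv; dy is HW x Cout (consumed in place)
static void conv3_backward(ConvCache& c, const mat& Wt, mat&& dy, bool relu,
                           mat& dW, vec& db, cube& dx) {
  if (relu) dy %= conv_to<mat>::from(c.act);
  dW = c.xcol.t() * dy;
  db = sum(dy, 0).t();
  mat dxcol = dy * Wt.t();
  c.xcol.reset();
  dx = col2im3(dxcol, c.H, c.W, c.Cin);
}

static cube maxpool2(const cube& x, ucube& arg) {
  const uword H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  arg.set_size(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v00 = x(2 * i, 2 * j, c),     v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        double m = v00; uword a = 0;
        if (v10 > m) { m = v10; a = 1; }
        if (v01 > m) { m = v01; a = 2; }
        if (v11 > m) { m = v11; a = 3; }
        out(i, j, c) = m; arg(i, j, c) = a;
      }
  return out;
}

static cube maxpool2_backward(const cube& dy, const ucube& arg,
                              uword H, uword W) {
  cube dx(H, W, dy.n_slices, fill::zeros);
  for (uword c = 0; c < dy.n_slices; ++c)
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i) {
        uword a = arg(i, j, c);
        dx(2 * i + (a & 1u), 2 * j + (a >> 1), c) = dy(i, j, c);
      }
  return dx;
}

static cube upsample2(const cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;     out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upsample2_backward(const cube& dy) {
  cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c)
    for (uword j = 0; j < dx.n_cols; ++j)
      for (uword i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

static cube dropout_mask(uword H, uword W, uword C, double rate,
                         std::mt19937_64& rng) {
  cube m(H, W, C);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double keep = 1.0 - rate;
  double* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i)
    p[i] = (U(rng) < keep) ? 1.0 / keep : 0.0;
  return m;
}

// softmax over columns of z (rows = pixels)
static mat softmax_rows(const mat& z) {
  vec mx = max(z, 1);
  mat e = exp(z.each_col() - mx);
  vec s = sum(e, 1);
  return e.each_col() / s;
}

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
  int depth;
};

static Net unpack(const Rcpp::List& weights, int depth) {
  Net net;
  Rcpp::List Wl = weights["W"], bl = weights["b"];
  for (int i = 0; i < Wl.size(); ++i) {
    net.W.push_back(Rcpp::as<mat>(Wl[i]));
    net.b.push_back(Rcpp::as<vec>(bl[i]));
  }
  net.depth = depth;
  return net;
}

struct ForwardState {
  std::vector<ConvCache> caches;        // one per 3x3 conv, in layer order
  std::vector<cube> skips;              // post-block encoder activations
  std::vector<ucube> poolArgs;
  std::vector<cube> dropMasks;
  mat headX, probs;                     // head input (HW x C), probabilities
  uword H = 0, W = 0;
};

// full forward pass; when train, applies inverted dropout after each pool.
// with_cache keeps the per-layer state the backward pass needs.
static void forward(const Net& net, const cube& x, bool train,
                    double dropout_rate, uint64_t seed, bool with_cache,
                    ForwardState& st) {
  std::mt19937_64 rng(seed);
  const int n3 = 2 * net.depth + 2 + 2 * net.depth;  // 3x3 convs
  if (with_cache) st.caches.resize(n3);
  int li = 0;
  cube cur = x;
  st.H = x.n_rows; st.W = x.n_cols;
  auto cache = [&](int i) -> ConvCache* {
    return with_cache ? &st.caches[i] : nullptr;
  };
  for (int k = 0; k < net.depth; ++k) {
    cur = conv3(cur, net.W[li], net.b[li], true, cache(li)); ++li;
    cur = conv3(cur, net.W[li], net.b[li], true, cache(li)); ++li;
    st.skips.push_back(cur);
    ucube arg;
    cur = maxpool2(cur, arg);
    if (with_cache) st.poolArgs.push_back(std::move(arg));
    if (train && dropout_rate > 0) {
      cube m = dropout_mask(cur.n_rows, cur.n_cols, cur.n_slices,
                            dropout_rate, rng);
      cur %= m;
      if (with_cache) st.dropMasks.push_back(std::move(m));
    }
  }
  cur = conv3(cur, net.W[li], net.b[li], true, cache(li)); ++li;
  cur = conv3(cur, net.W[li], net.b[li], true, cache(li)); ++li;
  for (int k = net.depth - 1; k >= 0; --k) {
    cur = upsample2(cur);
    cur = conv3(cur, net.W[li], net.b[li], true, cache(li)); ++li;
    cube cat = join_slices(st.skips[k], cur);
    cur = conv3(cat, net.W[li], net.b[li], true, cache(li)); ++li;
  }
  // 1x1 head + softmax
  st.headX = cube2mat(cur);
  mat z = st.headX * net.W[li];
  z.each_row() += net.b[li].t();
  st.probs = softmax_rows(z);
}

// [[Rcpp::export(name = ".cpp_unet_forward")]]
arma::cube cpp_unet_forward(const arma::cube& x, const Rcpp::List& weights,
                            int depth) {
  Net net = unpack(weights, depth);
  ForwardState st;
  forward(net, x, false, 0.0, 0, false, st);
  return mat2cube(st.probs, x.n_rows, x.n_cols);
}

// weighted CE + soft-Dice loss on probability rows; fills the gradient wrt
// probabilities. y is the 0-based class per pixel.
static double loss_and_dprob(const mat& probs, const uvec& y,
                             const vec& class_w, double mix, bool want_grad,
                             mat& dprob, double& ce_out, double& dice_out) {
  const uword n = probs.n_rows, C = probs.n_cols;
  const double eps = 1e-6;
  vec sum_t(C, fill::zeros), sum_pt(C, fill::zeros);
  vec sum_p = sum(probs, 0).t();
  vec py(n), wy(n);
  for (uword i = 0; i < n; ++i) {
    py(i) = probs(i, y(i));
    wy(i) = class_w(y(i));
    sum_t(y(i)) += 1.0;
    sum_pt(y(i)) += py(i);
  }
  double wsum = accu(class_w);
  double ce = accu(wy % (-log(clamp(py, 1e-12, 1.0)))) / n;
  vec denom = sum_p + sum_t + eps;
  vec dice_c = (2.0 * sum_pt + eps) / denom;
  double dice_term = 1.0 - accu(class_w % dice_c) / wsum;
  double total = mix * ce + (1.0 - mix) * dice_term;
  ce_out = ce; dice_out = dice_term;
  if (!want_grad) return total;

  dprob.zeros(n, C);
  vec coefA = 2.0 / denom;                              // multiplies t_ic
  vec coefB = (2.0 * sum_pt + eps) / (denom % denom);   // constant per class
  double scale = (1.0 - mix) / wsum;
  // dice part: d(1 - sum w D / wsum)/dp_{i,c} = -scale w_c (A_c t_ic - B_c)
  for (uword c = 0; c < C; ++c)
    dprob.col(c) += scale * class_w(c) * coefB(c);
  for (uword i = 0; i < n; ++i) {
    uword c = y(i);
    dprob(i, c) -= scale * class_w(c) * coefA(c);
    // CE part
    dprob(i, c) -= mix * wy(i) / (n * std::max(py(i), 1e-12));
  }
  return total;
}

// [[Rcpp::export(name = ".cpp_unet_loss")]]
Rcpp::List cpp_unet_loss(const arma::mat& probs, const arma::uvec& y0,
                         const arma::vec& class_w, double mix) {
  mat dprob; double ce, dice;
  double total = loss_and_dprob(probs, y0, class_w, mix, false, dprob,
                                ce, dice);
  return Rcpp::List::create(Rcpp::Named("loss") = total,
                            Rcpp::Named("ce") = ce,
                            Rcpp::Named("dice_term") = dice);
}

// [[Rcpp::export(name = ".cpp_unet_grad")]]
Rcpp::List cpp_unet_grad(const arma::cube& x, const arma::umat& y,
                         const Rcpp::List& weights, int depth,
                         const arma::vec& class_w, double mix,
                         double dropout_rate, double seed) {
  Net net = unpack(weights, depth);
  ForwardState st;
  forward(net, x, dropout_rate > 0, dropout_rate, (uint64_t) seed, true, st);
  uvec yv = vectorise(y);
  mat dprob; double ce, dice;
  double total = loss_and_dprob(st.probs, yv, class_w, mix, true, dprob,
                                ce, dice);

  // softmax backward: dz = p % (g - rowsum(g % p))
  vec inner = sum(dprob % st.probs, 1);
  mat dz = st.probs % (dprob.each_col() - inner);

  const int n_layers = (int) net.W.size();
  std::vector<mat> dW(n_layers);
  std::vector<vec> db(n_layers);

  int li = n_layers - 1;                 // 1x1 head
  dW[li] = st.headX.t() * dz;
  db[li] = sum(dz, 0).t();
  mat dflat = dz * net.W[li].t();
  cube dcur = mat2cube(dflat, st.H, st.W);
  --li;

  int ci = (int) st.caches.size() - 1;
  std::vector<cube> dskip(net.depth);
  // decoder blocks in reverse build order (full resolution first)
  for (int k = 0; k < net.depth; ++k) {
    cube dcat;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dcur), true,
                   dW[li], db[li], dcat);
    --li;
    uword cs = st.skips[k].n_slices;
    dskip[k] = dcat.slices(0, cs - 1);
    cube dup = dcat.slices(cs, dcat.n_slices - 1);
    cube dpre_up;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dup), true,
                   dW[li], db[li], dpre_up);
    --li;
    dcur = upsample2_backward(dpre_up);
  }
  {
    cube dtmp;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dcur), true,
                   dW[li], db[li], dtmp); --li;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dtmp), true,
                   dW[li], db[li], dcur); --li;
  }
  for (int k = net.depth - 1; k >= 0; --k) {
    if (dropout_rate > 0) dcur %= st.dropMasks[k];
    cube dpool = maxpool2_backward(dcur, st.poolArgs[k],
                                   st.skips[k].n_rows, st.skips[k].n_cols);
    dpool += dskip[k];
    cube dtmp;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dpool), true,
                   dW[li], db[li], dtmp); --li;
    conv3_backward(st.caches[ci--], net.W[li], cube2mat(dtmp), true,
                   dW[li], db[li], dcur); --li;
  }

  Rcpp::List dWl(n_layers), dbl(n_layers);
  for (int i = 0; i < n_layers; ++i) {
    dWl[i] = dW[i]; dbl[i] = db[i];
  }
  return Rcpp::List::create(Rcpp::Named("loss") = total,
                            Rcpp::Named("ce") = ce,
                            Rcpp::Named("dice_term") = dice,
                            Rcpp::Named("dW") = dWl,
                            Rcpp::Named("db") = dbl);
}
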