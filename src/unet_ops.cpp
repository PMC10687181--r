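// Low-level kernels for the U-Net segmenter: same-padding 3x3 convolution
// via im2col + GEMM, 2x2 max pooling, nearest-neighbour 2x upsampling, and
// the pixel-wise weighted softmax cross-entropy. Compute is single
// precision (ample for these nets, twice the GEMM throughput); parameters
// and gradients cross the R boundary as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat im2col3(const arma::fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::fmat out(static_cast<size_t>(H) * W, 9 * static_cast<size_t>(C));
  size_t col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        arma::fmat sh(H, W, arma::fill::zeros);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i1 >= i0 && j1 >= j0)
          sh.submat(i0, j0, i1, j1) =
            x.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
        out.col(col++) = arma::vectorise(sh);
      }
    }
  }
  return out;
}

static arma::fcube col2im3(const arma::fmat& dcol, int H, int W, int C) {
  arma::fcube dx(H, W, C, arma::fill::zeros);
  size_t col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        arma::fmat g = arma::reshape(dcol.col(col++), H, W);
        const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        if (i1 >= i0 && j1 >= j0)
          dx.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
            g.submat(i0, j0, i1, j1);
      }
    }
  }
  return dx;
}

static arma::fcube to_f(const arma::cube& x) {
  return arma::conv_to<arma::fcube>::from(x);
}
static arma::cube to_d(const arma::fcube& x) {
  return arma::conv_to<arma::cube>::from(x);
}

// [[Rcpp::export(name = ".conv3_fwd")]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int K = w.n_cols;
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  arma::fmat y = im2col3(to_f(x)) * wf;
  y.each_row() += bf;
  arma::fcube out(H, W, K);
  for (int k = 0; k < K; ++k) out.slice(k) = arma::reshape(y.col(k), H, W);
  return to_d(out);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(const arma::cube& x, const arma::mat& w,
               const arma::cube& dout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = dout.n_slices;
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::fcube df = to_f(dout);
  arma::fmat dmat(static_cast<size_t>(H) * W, K);
  for (int k = 0; k < K; ++k) dmat.col(k) = arma::vectorise(df.slice(k));
  arma::fmat col = im2col3(to_f(x));
  arma::fmat dW = col.t() * dmat;
  arma::frowvec db = arma::sum(dmat, 0);
  arma::fcube dx = col2im3(dmat * wf.t(), H, W, C);
  return List::create(
    _["dx"] = to_d(dx),
    _["dW"] = arma::conv_to<arma::mat>::from(dW),
    _["db"] = arma::conv_to<arma::vec>::from(db.t()));
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        const double v1 = x(2 * i + 1, 2 * j, c);
        const double v2 = x(2 * i, 2 * j + 1, c);
        const double v3 = x(2 * i + 1, 2 * j + 1, c);
        if (v1 > best) { best = v1; arg = 1; }
        if (v2 > best) { best = v2; arg = 2; }
        if (v3 > best) { best = v3; arg = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::icube& idx, const arma::cube& dout) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, c);
        dx(2 * i + (a % 2), 2 * j + (a / 2), c) = dout(i, j, c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd(const arma::cube& dout) {
  const int Ho = dout.n_rows / 2, Wo = dout.n_cols / 2, C = dout.n_slices;
  arma::cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        dx(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                      dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return dx;
}

// Weighted pixel-wise softmax cross-entropy. `labels` are 0-based class
// indices; loss and gradient are normalised by the total label weight so
// the gradient scale is independent of class balance settings.
// [[Rcpp::export(name = ".softmax_xent")]]
List softmax_xent(const arma::cube& logits, const IntegerMatrix& labels,
                  const arma::vec& weights) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  arma::cube grad(H, W, K);
  IntegerMatrix pred(H, W);
  double loss = 0.0, wsum = 0.0;
  long correct = 0;
  std::vector<double> p(K);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double mx = logits(i, j, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, logits(i, j, k));
      double s = 0.0;
      for (int k = 0; k < K; ++k) { p[k] = std::exp(logits(i, j, k) - mx); s += p[k]; }
      int arg = 0; double best = p[0];
      for (int k = 0; k < K; ++k) {
        p[k] /= s;
        if (p[k] > best) { best = p[k]; arg = k; }
      }
      const int y = labels(i, j);
      const double wy = weights(y);
      wsum += wy;
      loss -= wy * std::log(std::max(p[y], 1e-12));
      for (int k = 0; k < K; ++k)
        grad(i, j, k) = wy * (p[k] - (k == y ? 1.0 : 0.0));
      pred(i, j) = arg;
      if (arg == y) ++correct;
    }
  }
  if (wsum <= 0.0) wsum = 1.0;
  grad /= wsum;
  return List::create(_["loss"] = loss / wsum, _["grad"] = grad,
                      _["pred"] = pred,
                      _["pixel_accuracy"] =
                        static_cast<double>(correct) / (H * W));
}

// [[Rcpp::export(name = ".softmax_probs")]]
arma::cube softmax_probs(const arma::cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  arma::cube p(H, W, K);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double mx = logits(i, j, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, logits(i, j, k));
      double s = 0.0;
      for (int k = 0; k < K; ++k) { p(i, j, k) = std::exp(logits(i, j, k) - mx); s += p(i, j, k); }
      for (int k = 0; k < K; ++k) p(i, j, k) /= s;
    }
  }
  return p;
}

// [[Rcpp::export(name = ".logits_argmax")]]
IntegerMatrix logits_argmax(const arma::cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int arg = 0; double best = logits(i, j, 0);
      for (int k = 1; k < K; ++k)
        if (logits(i, j, k) > best) { best = logits(i, j, k); arg = k; }
      out(i, j) = arg;
    }
  }
  return out;
}

// Hot paths of the synthetic renderer: canvas assembly and 8-bit snapping
// (pure-R versions dominate cohort rendering time at 2048x1280).

// [[Rcpp::export(name = ".quantize8_cpp")]]
NumericVector quantize8_cpp(const NumericVector& x) {
  NumericVector out(x.size());
  const double* in = REAL(x);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = in[i];
    if (v < 0) v = 0; else if (v > 1) v = 1;
    o[i] = static_cast<int>(v * 255.0 + 0.5) / 255.0;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".tiled_canvas")]]
NumericVector tiled_canvas(int H, int W, const NumericVector& tile, int t,
                           const NumericVector& bg) {
  NumericVector out = no_init(static_cast<R_xlen_t>(H) * W * 3);
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  const R_xlen_t tplane = static_cast<R_xlen_t>(t) * t;
  for (int ch = 0; ch < 3; ++ch) {
    const double b = bg[ch];
    for (int j = 0; j < W; ++j) {
      const R_xlen_t tcol = static_cast<R_xlen_t>(j % t) * t + ch * tplane;
      double* col = REAL(out) + ch * plane + static_cast<R_xlen_t>(j) * H;
      const double* tc = REAL(tile) + tcol;
      int i = 0;
      while (i < H) {
        const int n = std::min(t, H - i);
        for (int k = 0; k < n; ++k) {
          double v = b + tc[k];
          if (v < 0) v = 0; else if (v > 1) v = 1;
          col[i + k] = static_cast<int>(v * 255.0 + 0.5) / 255.0;
        }
        i += n;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, 3);
  return out;
}


// Scatter element colours into the canvas, quantizing to 8-bit levels as
// they land: `idx` is 1-based into the H x W plane, `vals` holds the three
// channels back to back. Mutates `image` in place -- callers own the only
// reference (the canvas was freshly built by .tiled_canvas).
// [[Rcpp::export(name = ".scatter_paint")]]
NumericVector scatter_paint(NumericVector image, const IntegerVector& idx,
                            const NumericVector& vals, R_xlen_t plane) {
  double* o = REAL(image);
  const double* v = REAL(vals);
  const int* id = INTEGER(idx);
  const R_xlen_t n = idx.size();
  for (int ch = 0; ch < 3; ++ch) {
    double* base = o + ch * plane;
    const double* vc = v + ch * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      double x = vc[i];
      if (x < 0) x = 0; else if (x > 1) x = 1;
      base[id[i] - 1] = static_cast<int>(x * 255.0 + 0.5) / 255.0;
    }
  }
  return image;
}

// ---- fused network passes -------------------------------------------------
// The layer-by-layer R orchestration spends most of its time converting
// activations between double and float and re-building im2col matrices in
// the backward pass. These fused passes keep every activation and column
// matrix in single precision for the lifetime of one call.

static const double NORM_CENTER = 0.8;
static const double NORM_SCALE = 0.15;

static arma::fmat get_w(const List& p, const std::string& nm) {
  arma::mat m = as<arma::mat>(p[nm]);
  return arma::conv_to<arma::fmat>::from(m);
}
static arma::frowvec get_b(const List& p, const std::string& nm) {
  arma::vec v = as<arma::vec>(p[nm]);
  return arma::conv_to<arma::frowvec>::from(v.t());
}

static void relu_inplace(arma::fmat& m) {
  float* q = m.memptr();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) if (q[i] < 0) q[i] = 0;
}

static arma::fcube mat_to_cube(const arma::fmat& m, int H, int W) {
  arma::fcube out(H, W, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), sizeof(float) * m.n_elem);
  return out;
}
static arma::fmat cube_to_mat(const arma::fcube& c) {
  return arma::fmat(const_cast<float*>(c.memptr()),
                    c.n_rows * c.n_cols, c.n_slices, true);
}

static arma::fcube fpool2(const arma::fcube& x, arma::icube& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::fcube y(Ho, Wo, C);
  idx.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        float best = x(2 * i, 2 * j, c);
        int arg = 0;
        float v = x(2 * i + 1, 2 * j, c);
        if (v > best) { best = v; arg = 1; }
        v = x(2 * i, 2 * j + 1, c);
        if (v > best) { best = v; arg = 2; }
        v = x(2 * i + 1, 2 * j + 1, c);
        if (v > best) { best = v; arg = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = arg;
      }
  return y;
}

static arma::fcube fpool2_bwd(const arma::icube& idx, const arma::fcube& d) {
  const int Ho = d.n_rows, Wo = d.n_cols, C = d.n_slices;
  arma::fcube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, c);
        dx(2 * i + (a % 2), 2 * j + (a / 2), c) = d(i, j, c);
      }
  return dx;
}

static arma::fcube fup2(const arma::fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::fcube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const float v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static arma::fcube fup2_bwd(const arma::fcube& d) {
  const int Ho = d.n_rows / 2, Wo = d.n_cols / 2, C = d.n_slices;
  arma::fcube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(i, j, c) = d(2 * i, 2 * j, c) + d(2 * i + 1, 2 * j, c) +
                      d(2 * i, 2 * j + 1, c) + d(2 * i + 1, 2 * j + 1, c);
  return dx;
}

static arma::fcube normalize_input(const arma::cube& x) {
  arma::fcube out(x.n_rows, x.n_cols, x.n_slices);
  const double* in = x.memptr();
  float* o = out.memptr();
  for (size_t i = 0; i < x.n_elem; ++i)
    o[i] = static_cast<float>((in[i] - NORM_CENTER) / NORM_SCALE);
  return out;
}

struct FwdState {
  std::vector<arma::fmat> e_col1, e_col2, d_col1, d_col2, up_mat;
  std::vector<arma::fcube> e_a1, e_a2, d_a1, d_a2;
  std::vector<arma::icube> pool_idx;
  arma::fmat head_in;   // HW x f1
  arma::fcube logits;
};

static void unet_forward_f(const List& params, const arma::cube& x,
                           int depth, FwdState& st, bool keep_cols) {
  char nm[32];
  st.e_col1.resize(depth); st.e_col2.resize(depth);
  st.e_a1.resize(depth); st.e_a2.resize(depth);
  st.pool_idx.resize(depth);
  st.d_col1.resize(depth); st.d_col2.resize(depth);
  st.d_a1.resize(depth); st.d_a2.resize(depth);
  st.up_mat.resize(depth);
  arma::fcube cur = normalize_input(x);
  for (int l = 1; l <= depth; ++l) {
    const int H = cur.n_rows, W = cur.n_cols;
    arma::fmat col = im2col3(cur);
    snprintf(nm, sizeof(nm), "e%d.W1", l);
    arma::fmat z = col * get_w(params, nm);
    snprintf(nm, sizeof(nm), "e%d.b1", l);
    z.each_row() += get_b(params, nm);
    relu_inplace(z);
    if (keep_cols) st.e_col1[l - 1] = std::move(col);
    st.e_a1[l - 1] = mat_to_cube(z, H, W);
    arma::fmat col2 = im2col3(st.e_a1[l - 1]);
    snprintf(nm, sizeof(nm), "e%d.W2", l);
    arma::fmat z2 = col2 * get_w(params, nm);
    snprintf(nm, sizeof(nm), "e%d.b2", l);
    z2.each_row() += get_b(params, nm);
    relu_inplace(z2);
    if (keep_cols) st.e_col2[l - 1] = std::move(col2);
    st.e_a2[l - 1] = mat_to_cube(z2, H, W);
    if (l < depth) {
      cur = fpool2(st.e_a2[l - 1], st.pool_idx[l - 1]);
    } else {
      cur = st.e_a2[l - 1];
    }
  }
  for (int l = depth - 1; l >= 1; --l) {
    arma::fcube up = fup2(cur);
    const int H = up.n_rows, W = up.n_cols;
    arma::fmat upm = cube_to_mat(up);
    snprintf(nm, sizeof(nm), "u%d.W", l);
    arma::fmat prm = upm * get_w(params, nm);
    snprintf(nm, sizeof(nm), "u%d.b", l);
    prm.each_row() += get_b(params, nm);
    if (keep_cols) st.up_mat[l - 1] = std::move(upm);
    const arma::fcube& skip = st.e_a2[l - 1];
    arma::fcube cat(H, W, prm.n_cols + skip.n_slices);
    std::memcpy(cat.memptr(), prm.memptr(), sizeof(float) * prm.n_elem);
    std::memcpy(cat.memptr() + prm.n_elem, skip.memptr(),
                sizeof(float) * skip.n_elem);
    arma::fmat col = im2col3(cat);
    snprintf(nm, sizeof(nm), "d%d.W1", l);
    arma::fmat z = col * get_w(params, nm);
    snprintf(nm, sizeof(nm), "d%d.b1", l);
    z.each_row() += get_b(params, nm);
    relu_inplace(z);
    if (keep_cols) st.d_col1[l - 1] = std::move(col);
    st.d_a1[l - 1] = mat_to_cube(z, H, W);
    arma::fmat col2 = im2col3(st.d_a1[l - 1]);
    snprintf(nm, sizeof(nm), "d%d.W2", l);
    arma::fmat z2 = col2 * get_w(params, nm);
    snprintf(nm, sizeof(nm), "d%d.b2", l);
    z2.each_row() += get_b(params, nm);
    relu_inplace(z2);
    if (keep_cols) st.d_col2[l - 1] = std::move(col2);
    st.d_a2[l - 1] = mat_to_cube(z2, H, W);
    cur = st.d_a2[l - 1];
  }
  const int H = cur.n_rows, W = cur.n_cols;
  st.head_in = cube_to_mat(cur);
  arma::fmat lm = st.head_in * get_w(params, "out.W");
  lm.each_row() += get_b(params, "out.b");
  st.logits = mat_to_cube(lm, H, W);
}

// Argmax prediction (and optional logits) for one tile.
// [[Rcpp::export(name = ".unet_infer")]]
List unet_infer(const List& params, const arma::cube& x, int depth,
                bool want_logits) {
  FwdState st;
  unet_forward_f(params, x, depth, st, false);
  const int H = st.logits.n_rows, W = st.logits.n_cols,
            K = st.logits.n_slices;
  IntegerMatrix pred(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int arg = 0;
      float best = st.logits(i, j, 0);
      for (int k = 1; k < K; ++k)
        if (st.logits(i, j, k) > best) { best = st.logits(i, j, k); arg = k; }
      pred(i, j) = arg;
    }
  if (!want_logits) return List::create(_["pred"] = pred);
  return List::create(
    _["pred"] = pred,
    _["logits"] = arma::conv_to<arma::cube>::from(st.logits));
}

// One full training step for one tile: forward, weighted softmax
// cross-entropy, backward; returns the loss, the pixel accuracy of the
// forward pass, and the gradient for every parameter.
// [[Rcpp::export(name = ".unet_step")]]
List unet_step(const List& params, const arma::cube& x,
               const IntegerMatrix& labels, const arma::vec& weights,
               int depth) {
  char nm[32];
  FwdState st;
  unet_forward_f(params, x, depth, st, true);
  const int H = st.logits.n_rows, W = st.logits.n_cols,
            K = st.logits.n_slices;

  // loss + dlogits
  arma::fmat dlm(static_cast<size_t>(H) * W, K);
  double loss = 0.0, wsum = 0.0;
  long correct = 0;
  std::vector<float> p(K);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      float mx = st.logits(i, j, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, st.logits(i, j, k));
      float s = 0.0f;
      for (int k = 0; k < K; ++k) {
        p[k] = std::exp(st.logits(i, j, k) - mx);
        s += p[k];
      }
      int arg = 0; float best = p[0];
      for (int k = 0; k < K; ++k) {
        p[k] /= s;
        if (p[k] > best) { best = p[k]; arg = k; }
      }
      const int y = labels(i, j);
      const double wy = weights(y);
      wsum += wy;
      loss -= wy * std::log(std::max(static_cast<double>(p[y]), 1e-12));
      const size_t row = static_cast<size_t>(j) * H + i;
      for (int k = 0; k < K; ++k)
        dlm(row, k) = static_cast<float>(wy) * (p[k] - (k == y ? 1.0f : 0.0f));
      if (arg == y) ++correct;
    }
  if (wsum <= 0.0) wsum = 1.0;
  loss /= wsum;
  dlm /= static_cast<float>(wsum);

  List grads;
  grads["out.W"] = arma::conv_to<arma::mat>::from(
    arma::fmat(st.head_in.t() * dlm));
  grads["out.b"] = arma::conv_to<arma::vec>::from(
    arma::frowvec(arma::sum(dlm, 0)).t());
  arma::fmat wout = get_w(params, "out.W");
  arma::fcube dcur = mat_to_cube(dlm * wout.t(), H, W);

  std::vector<arma::fcube> dskip(depth);
  auto conv_bwd_cached = [&](const arma::fmat& col, const arma::fmat& w,
                             const arma::fcube& dout, arma::fmat& dW,
                             arma::frowvec& db, arma::fcube& dx,
                             bool need_dx) {
    arma::fmat dmat = cube_to_mat(dout);
    dW = col.t() * dmat;
    db = arma::sum(dmat, 0);
    if (need_dx)
      dx = col2im3(dmat * w.t(), dout.n_rows, dout.n_cols, w.n_rows / 9);
  };

  for (int l = 1; l <= depth - 1; ++l) {   // decoder ran depth-1..1
    // relu masks: a > 0
    arma::fcube dz2 = dcur;
    {
      const float* a = st.d_a2[l - 1].memptr();
      float* g = dz2.memptr();
      for (size_t i = 0; i < dz2.n_elem; ++i) if (a[i] <= 0) g[i] = 0;
    }
    arma::fmat dW; arma::frowvec db; arma::fcube dx;
    snprintf(nm, sizeof(nm), "d%d.W2", l);
    conv_bwd_cached(st.d_col2[l - 1], get_w(params, nm), dz2, dW, db, dx, true);
    grads[nm] = arma::conv_to<arma::mat>::from(dW);
    snprintf(nm, sizeof(nm), "d%d.b2", l);
    grads[nm] = arma::conv_to<arma::vec>::from(db.t());
    arma::fcube dz1 = dx;
    {
      const float* a = st.d_a1[l - 1].memptr();
      float* g = dz1.memptr();
      for (size_t i = 0; i < dz1.n_elem; ++i) if (a[i] <= 0) g[i] = 0;
    }
    snprintf(nm, sizeof(nm), "d%d.W1", l);
    arma::fmat w1 = get_w(params, nm);
    conv_bwd_cached(st.d_col1[l - 1], w1, dz1, dW, db, dx, true);
    grads[nm] = arma::conv_to<arma::mat>::from(dW);
    snprintf(nm, sizeof(nm), "d%d.b1", l);
    grads[nm] = arma::conv_to<arma::vec>::from(db.t());
    // split concat gradient: projected channels then skip channels
    snprintf(nm, sizeof(nm), "u%d.W", l);
    arma::fmat uw = get_w(params, nm);
    const int cp = uw.n_cols;
    const int cs = dx.n_slices - cp;
    const int uh = dx.n_rows, uwd = dx.n_cols;
    arma::fcube dproj = dx.slices(0, cp - 1);
    dskip[l - 1] = dx.slices(cp, cp + cs - 1);
    arma::fmat dprm = cube_to_mat(dproj);
    grads[nm] = arma::conv_to<arma::mat>::from(
      arma::fmat(st.up_mat[l - 1].t() * dprm));
    snprintf(nm, sizeof(nm), "u%d.b", l);
    grads[nm] = arma::conv_to<arma::vec>::from(
      arma::frowvec(arma::sum(dprm, 0)).t());
    arma::fcube dup = mat_to_cube(dprm * uw.t(), uh, uwd);
    dcur = fup2_bwd(dup);
  }

  arma::fcube d_above;
  for (int l = depth; l >= 1; --l) {
    arma::fcube d_a2 = (l == depth) ? dcur
      : arma::fcube(fpool2_bwd(st.pool_idx[l - 1], d_above) + dskip[l - 1]);
    {
      const float* a = st.e_a2[l - 1].memptr();
      float* g = d_a2.memptr();
      for (size_t i = 0; i < d_a2.n_elem; ++i) if (a[i] <= 0) g[i] = 0;
    }
    arma::fmat dW; arma::frowvec db; arma::fcube dx;
    snprintf(nm, sizeof(nm), "e%d.W2", l);
    conv_bwd_cached(st.e_col2[l - 1], get_w(params, nm), d_a2, dW, db, dx, true);
    grads[nm] = arma::conv_to<arma::mat>::from(dW);
    snprintf(nm, sizeof(nm), "e%d.b2", l);
    grads[nm] = arma::conv_to<arma::vec>::from(db.t());
    arma::fcube dz1 = dx;
    {
      const float* a = st.e_a1[l - 1].memptr();
      float* g = dz1.memptr();
      for (size_t i = 0; i < dz1.n_elem; ++i) if (a[i] <= 0) g[i] = 0;
    }
    snprintf(nm, sizeof(nm), "e%d.W1", l);
    conv_bwd_cached(st.e_col1[l - 1], get_w(params, nm), dz1, dW, db, dx,
                    l > 1);
    grads[nm] = arma::conv_to<arma::mat>::from(dW);
    snprintf(nm, sizeof(nm), "e%d.b1", l);
    grads[nm] = arma::conv_to<arma::vec>::from(db.t());
    if (l > 1) d_above = dx;
  }

  double acc = static_cast<double>(correct) /
               (static_cast<double>(H) * W);
  return List::create(_["loss"] = loss, _["grad"] = grads,
                      _["pixel_accuracy"] = acc);
}


// Row-major patch extraction (image tiles and mask tiles); equivalent to
// repeated R subsetting but with one allocation + memcpy per tile.
// [[Rcpp::export(name = ".extract_tiles3")]]
List extract_tiles3(const NumericVector& image, int H, int W, int ps) {
  const int nr = H / ps, nc = W / ps;
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  List out(nr * nc);
  int k = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      NumericVector tile = no_init(static_cast<R_xlen_t>(ps) * ps * 3);
      double* t = REAL(tile);
      for (int ch = 0; ch < 3; ++ch) {
        const double* base = REAL(image) + ch * plane +
          static_cast<R_xlen_t>(c) * ps * H + static_cast<R_xlen_t>(r) * ps;
        double* tb = t + static_cast<R_xlen_t>(ch) * ps * ps;
        for (int j = 0; j < ps; ++j)
          std::memcpy(tb + static_cast<R_xlen_t>(j) * ps,
                      base + static_cast<R_xlen_t>(j) * H,
                      sizeof(double) * ps);
      }
      tile.attr("dim") = IntegerVector::create(ps, ps, 3);
      out[k++] = tile;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".extract_tiles2")]]
List extract_tiles2(const IntegerMatrix& m, int ps) {
  const int H = m.nrow(), W = m.ncol();
  const int nr = H / ps, nc = W / ps;
  List out(nr * nc);
  int k = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      IntegerMatrix tile(ps, ps);
      for (int j = 0; j < ps; ++j)
        std::memcpy(&tile(0, j), &m(r * ps, c * ps + j),
                    sizeof(int) * ps);
      out[k++] = tile;
    }
  }
  return out;
}
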