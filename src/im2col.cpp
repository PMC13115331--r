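#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (channels) x (H * W * B) matrices, spatial index fastest
// (column-major within a sample). im2col stacks the 9 dilated 3x3 tap
// sources of every output position into a (9 * channels) x (H * W * B)
// matrix (zero where a tap falls outside the sample), so a dilated
// convolution becomes a single GEMM. col2im is its adjoint (scatter-add).
// Loops run position-major so writes are contiguous.

static NumericMatrix alloc_noinit(int nr, int nc) {
  SEXP s = Rf_allocMatrix(REALSXP, nr, nc);
  return NumericMatrix(s);
}

// [[Rcpp::export]]
NumericMatrix im2col_3x3(const NumericMatrix& X, int H, int W, int B,
                         int dilation) {
  const int C = X.nrow();
  const int N = H * W * B;
  const int d = dilation;
  if (X.ncol() != N) stop("im2col: geometry mismatch");
  NumericMatrix out = alloc_noinit(9 * C, N);
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const int off = b * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst = o + (size_t)(off + w * H + h) * 9 * C;
        for (int dx = -d; dx <= d; dx += d) {
          const int ws = w + dx;
          const bool wok = (ws >= 0 && ws < W);
          for (int dy = -d; dy <= d; dy += d, dst += C) {
            const int hs = h + dy;
            if (wok && hs >= 0 && hs < H) {
              const double* src = x + (size_t)(off + ws * H + hs) * C;
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_3x3(const NumericMatrix& G, int H, int W, int B,
                         int dilation, int C) {
  const int N = H * W * B;
  const int d = dilation;
  if (G.ncol() != N || G.nrow() != 9 * C) stop("col2im: geometry mismatch");
  NumericMatrix out(C, N); // zero-initialized: accumulated into
  const double* g = G.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const int off = b * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* src = g + (size_t)(off + w * H + h) * 9 * C;
        for (int dx = -d; dx <= d; dx += d) {
          const int ws = w + dx;
          const bool wok = (ws >= 0 && ws < W);
          for (int dy = -d; dy <= d; dy += d, src += C) {
            const int hs = h + dy;
            if (wok && hs >= 0 && hs < H) {
              double* dst = o + (size_t)(off + ws * H + hs) * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// in-place ReLU; the argument must be a freshly allocated matrix
// [[Rcpp::export]]
NumericMatrix relu_inplace(NumericMatrix X) {
  double* x = X.begin();
  const size_t n = (size_t)X.nrow() * X.ncol();
  for (size_t i = 0; i < n; ++i) if (x[i] < 0) x[i] = 0;
  return X;
}

// in-place ReLU backward: zero G where the activation A is zero
// [[Rcpp::export]]
NumericMatrix relu_bwd_inplace(NumericMatrix G, const NumericMatrix& A) {
  double* g = G.begin();
  const double* a = A.begin();
  const size_t n = (size_t)G.nrow() * G.ncol();
  if ((size_t)A.nrow() * A.ncol() != n) stop("relu_bwd: shape mismatch");
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0) g[i] = 0;
  return G;
}

// global average pooling over space: (C, HW*B) -> (C, B)
// [[Rcpp::export]]
NumericMatrix gap_pool(const NumericMatrix& X, int HW, int B) {
  const int C = X.nrow();
  if (X.ncol() != (R_xlen_t)HW * B) stop("gap: geometry mismatch");
  NumericMatrix out(C, B);
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    double* ob = o + (size_t)b * C;
    for (int s = 0; s < HW; ++s) {
      const double* col = x + ((size_t)b * HW + s) * C;
      for (int c = 0; c < C; ++c) ob[c] += col[c];
    }
    for (int c = 0; c < C; ++c) ob[c] /= HW;
  }
  return out;
}

// adjoint of gap_pool: spread (C, B) over (C, HW*B), divided by HW
// [[Rcpp::export]]
NumericMatrix gap_unpool(const NumericMatrix& G, int HW, int B) {
  const int C = G.nrow();
  if (G.ncol() != B) stop("gap_unpool: geometry mismatch");
  NumericMatrix out = alloc_noinit(C, HW * B);
  const double* g = G.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* gb = g + (size_t)b * C;
    for (int s = 0; s < HW; ++s) {
      double* col = o + ((size_t)b * HW + s) * C;
      for (int c = 0; c < C; ++c) col[c] = gb[c] / HW;
    }
  }
  return out;
}

// in-place Adam update over parameter lists (params, grads, first/second
// moments must be congruent lists of numeric arrays)
// [[Rcpp::export]]
void adam_update(List params, const List& grads, List m, List v,
                 double lr, double beta1, double beta2, double eps, int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  CharacterVector nm = params.names();
  for (int k = 0; k < params.size(); ++k) {
    std::string key = as<std::string>(nm[k]);
    NumericVector p = params[k];
    NumericVector g = grads[key];
    NumericVector mk = m[key];
    NumericVector vk = v[key];
    const R_xlen_t n = p.size();
    if (g.size() != n) stop("adam: gradient shape mismatch");
    for (R_xlen_t i = 0; i < n; ++i) {
      mk[i] = beta1 * mk[i] + (1.0 - beta1) * g[i];
      vk[i] = beta2 * vk[i] + (1.0 - beta2) * g[i] * g[i];
      p[i] -= lr * (mk[i] / bc1) / (std::sqrt(vk[i] / bc2) + eps);
    }
  }
}

// regional (block) average pooling: (C, H*W*B) -> (C * gh * gw, B).
// Feature row order: block index (column-major over the gh x gw grid)
// major, channel minor.
// [[Rcpp::export]]
NumericMatrix block_pool(const NumericMatrix& X, int H, int W, int B,
                         int gh, int gw) {
  const int C = X.nrow();
  if (X.ncol() != (R_xlen_t)H * W * B || H % gh || W % gw)
    stop("block_pool: geometry mismatch");
  const int bh = H / gh, bw = W / gw;
  NumericMatrix out(C * gh * gw, B);
  const double* x = X.begin();
  double* o = out.begin();
  const double inv = 1.0 / (bh * bw);
  for (int b = 0; b < B; ++b) {
    double* ob = o + (size_t)b * C * gh * gw;
    for (int w = 0; w < W; ++w) {
      const int bx = w / bw;
      for (int h = 0; h < H; ++h) {
        const int by = h / bh;
        const double* col = x + ((size_t)b * H * W + (size_t)w * H + h) * C;
        double* dst = ob + (size_t)(bx * gh + by) * C;
        for (int c = 0; c < C; ++c) dst[c] += col[c] * inv;
      }
    }
  }
  return out;
}

// adjoint of block_pool
// [[Rcpp::export]]
NumericMatrix block_unpool(const NumericMatrix& G, int H, int W, int B,
                           int gh, int gw) {
  const int C = G.nrow() / (gh * gw);
  if (G.ncol() != B || G.nrow() != C * gh * gw)
    stop("block_unpool: geometry mismatch");
  const int bh = H / gh, bw = W / gw;
  NumericMatrix out(C, (R_xlen_t)H * W * B);
  const double* g = G.begin();
  double* o = out.begin();
  const double inv = 1.0 / (bh * bw);
  for (int b = 0; b < B; ++b) {
    const double* gb = g + (size_t)b * C * gh * gw;
    for (int w = 0; w < W; ++w) {
      const int bx = w / bw;
      for (int h = 0; h < H; ++h) {
        const int by = h / bh;
        const double* src = gb + (size_t)(bx * gh + by) * C;
        double* col = o + ((size_t)b * H * W + (size_t)w * H + h) * C;
        for (int c = 0; c < C; ++c) col[c] = src[c] * inv;
      }
    }
  }
  return out;
}
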