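// Computational kernels: separable Gaussian blur, connected-component
// labelling, anti-aliased ellipse rasterization, and the batched conv /
// max-pool primitives (plus per-channel moment helpers) that back the
// time-distributed CNN feature extractor.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- image ops

// Separable Gaussian blur with replicate-edge padding. radius = ceil(3*sigma).
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
arma::mat cpp_gaussian_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  int r = (int)std::ceil(3.0 * sigma);
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  int H = img.n_rows, W = img.n_cols;
  // replicate-pad, then accumulate shifted views (vectorized separable passes)
  arma::mat P(H + 2 * r, W + 2 * r);
  P.submat(r, r, r + H - 1, r + W - 1) = img;
  for (int d = 0; d < r; ++d) {
    P.row(d) = P.row(r);
    P.row(H + r + d) = P.row(H + r - 1);
  }
  for (int d = 0; d < r; ++d) {
    P.col(d) = P.col(r);
    P.col(W + r + d) = P.col(W + r - 1);
  }
  arma::mat tmp(H, W + 2 * r, arma::fill::zeros);
  for (int d = 0; d <= 2 * r; ++d) {
    tmp += k(d) * P.rows(d, d + H - 1);
  }
  arma::mat out(H, W, arma::fill::zeros);
  for (int d = 0; d <= 2 * r; ++d) {
    out += k(d) * tmp.cols(d, d + W - 1);
  }
  return out;
}

// 8-connected component labelling of a binary matrix; labels 1..K assigned in
// raster-scan order of each component's first pixel.
// [[Rcpp::export(name = ".cpp_label_components")]]
arma::imat cpp_label_components(const arma::imat& bin) {
  int H = bin.n_rows, W = bin.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (bin(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (bin(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Draw an anti-aliased filled ellipse into img (max-composited).
// (cx, cy) are 0-based pixel coordinates (x = column, y = row); a, b are the
// semi-axes in px; theta is the orientation of the a-axis in radians.
// [[Rcpp::export(name = ".cpp_add_ellipse")]]
void cpp_add_ellipse(NumericMatrix img, double cx, double cy, double a, double b,
                     double theta, double intensity) {
  int H = img.nrow(), W = img.ncol();
  double rmax = std::max(a, b) + 1.5;
  int j0 = std::max(0, (int)std::floor(cx - rmax));
  int j1 = std::min(W - 1, (int)std::ceil(cx + rmax));
  int i0 = std::max(0, (int)std::floor(cy - rmax));
  int i1 = std::min(H - 1, (int)std::ceil(cy + rmax));
  double ct = std::cos(theta), st = std::sin(theta);
  double scale = std::min(a, b);   // approximate signed-distance scale
  for (int j = j0; j <= j1; ++j) {
    for (int i = i0; i <= i1; ++i) {
      double dx = j - cx, dy = i - cy;
      double xr = (dx * ct + dy * st) / a;
      double yr = (-dx * st + dy * ct) / b;
      double r = std::sqrt(xr * xr + yr * yr);
      double d = (r - 1.0) * scale;              // px outside boundary
      double cov = 0.5 - d;
      if (cov <= 0) continue;
      if (cov > 1) cov = 1;
      double v = intensity * cov;
      if (v > img(i, j)) img(i, j) = v;
    }
  }
}

// ------------------------------------------------------------- NN primitives
// Batched activations are R arrays with dim (H, W, C, N); each n indexes one
// (sample, frame). Convolutions are 3x3 (or k x k), stride 1, zero-padded
// ("same"). Weight matrix layout: (k*k*Cin, Cout), feature index
// c*k*k + di*k + dj for offsets di, dj in [0, k).

static void im2col(const double* x, int H, int W, int C, int k, arma::mat& cols,
                   size_t row0 = 0) {
  int half = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        int col = c * k * k + di * k + dj;
        double* dst = cols.colptr(col) + row0;
        int oi = di - half, oj = dj - half;
        for (int j = 0; j < W; ++j) {
          int jj = j + oj;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) dst[i + j * H] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            int ii = i + oi;
            dst[i + j * H] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
          }
        }
      }
    }
  }
}

static void col2im_add_block(const arma::mat& cols, size_t row0, int H, int W,
                             int C, int k, double* dx) {
  int half = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        int col = c * k * k + di * k + dj;
        const double* src = cols.colptr(col) + row0;
        int oi = di - half, oj = dj - half;
        for (int j = 0; j < W; ++j) {
          int jj = j + oj;
          if (jj < 0 || jj >= W) continue;
          double* dstc = xc + (size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            int ii = i + oi;
            if (ii >= 0 && ii < H) dstc[ii] += src[i + j * H];
          }
        }
      }
    }
  }
}

// Convolution + bias + ReLU fused.
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector dims,
                           const arma::mat& Wt, const arma::vec& b, int k,
                           bool relu = true) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = Wt.n_cols;
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat y(out.begin() + (size_t)n * H * W * Cout, H * W, Cout,
                false, true);
    y = cols * Wt;
    y.each_row() += b.t();
    if (relu) {
      double* p = y.memptr();
      for (size_t i = 0; i < (size_t)H * W * Cout; ++i) if (p[i] < 0) p[i] = 0;
    }
  }
  return out;
}

// Backward of conv (+ fused ReLU using the post-activation output y):
// returns list(dx, dW, db); dx computation can be skipped for the first
// layer. im2col is recomputed to avoid caching the column matrices.
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, IntegerVector dims, const arma::mat& Wt,
                  NumericVector dy, NumericVector y, int k,
                  bool need_dx = true) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = Wt.n_cols;
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = dims;
  arma::mat dW(Wt.n_rows, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(H * W, k * k * C);
  arma::mat dz(H * W, Cout);
  arma::mat dcols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * H * W * Cout;
    const double* yn = y.begin() + (size_t)n * H * W * Cout;
    double* dzp = dz.memptr();
    for (size_t i = 0; i < (size_t)H * W * Cout; ++i) {
      dzp[i] = yn[i] > 0 ? dyn[i] : 0.0;   // ReLU mask
    }
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    dW += cols.t() * dz;                   // gemm(T, N), no copies
    db += arma::sum(dz, 0).t();
    if (need_dx) {
      dcols = dz * Wt.t();                 // (H*W, k*k*C)
      col2im_add_block(dcols, 0, H, W, C, k,
                       dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Batch-norm training forward, fused: per-channel batch moments + normalize.
// Returns list(out, mean, var).
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, IntegerVector dims, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& mean,
                const arma::vec& var, bool use_given, double eps) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t hw = (size_t)H * W;
  arma::vec m(C), v(C);
  if (use_given) {
    m = mean; v = var;
  } else {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + (size_t)n * hw * C + c * hw;
        for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double mu = s / (hw * N);
      m(c) = mu;
      v(c) = s2 / (hw * N) - mu * mu;
    }
  }
  NumericVector out(x.size());
  out.attr("dim") = dims;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = gamma(c) / std::sqrt(v(c) + eps);
      double sh = beta(c) - a * m(c);
      const double* p = x.begin() + (size_t)n * hw * C + c * hw;
      double* q = out.begin() + (size_t)n * hw * C + c * hw;
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + sh;
    }
  }
  return List::create(_["out"] = out, _["mean"] = m, _["var"] = v);
}

// Batch-norm backward (batch statistics), fused single implementation:
// dx = gamma*inv * (dy - mean(dy) - xhat * mean(xhat*dy)) when train=true,
// dx = gamma*inv * dy when train=false (frozen statistics).
// Returns list(dx, dgamma, dbeta).
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, IntegerVector dims,
                const arma::vec& gamma, const arma::vec& mean,
                const arma::vec& var, bool train, double eps) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  size_t hw = (size_t)H * W;
  double M = (double)hw * N;
  arma::vec inv = 1.0 / arma::sqrt(var + eps);
  arma::vec sum_dy(C, arma::fill::zeros), sum_xdy(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double a = 0, b = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + (size_t)n * hw * C + c * hw;
      const double* pd = dy.begin() + (size_t)n * hw * C + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        double xh = (px[i] - mean(c)) * inv(c);
        a += pd[i];
        b += xh * pd[i];
      }
    }
    sum_dy(c) = a;
    sum_xdy(c) = b;
  }
  NumericVector dx(x.size());
  dx.attr("dim") = dims;
  for (int c = 0; c < C; ++c) {
    double gi = gamma(c) * inv(c);
    double mdy = train ? sum_dy(c) / M : 0.0;
    double mxdy = train ? sum_xdy(c) / M : 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + (size_t)n * hw * C + c * hw;
      const double* pd = dy.begin() + (size_t)n * hw * C + c * hw;
      double* q = dx.begin() + (size_t)n * hw * C + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        double xh = (px[i] - mean(c)) * inv(c);
        q[i] = gi * (pd[i] - mdy - xh * mxdy);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = sum_xdy,
                      _["dbeta"] = sum_dy);
}

// Max pooling, pool size `size`, stride `stride`. Returns list(out, idx) where
// idx holds 0-based linear indices (within each n's H*W*C block) of the max.
// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims, int size, int stride) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  IntegerVector odim = IntegerVector::create(Ho, Wo, C, N);
  out.attr("dim") = odim;
  idx.attr("dim") = odim;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* on = out.begin() + (size_t)n * Ho * Wo * C;
    int* in_ = idx.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          int ib = io * stride, jb = jo * stride;
          double best = -1e300; int bidx = 0;
          for (int dj = 0; dj < size; ++dj) {
            for (int di = 0; di < size; ++di) {
              int p = (ib + di) + (jb + dj) * H;
              if (xc[p] > best) { best = xc[p]; bidx = p; }
            }
          }
          size_t q = (size_t)io + (size_t)jo * Ho + (size_t)c * Ho * Wo;
          on[q] = best;
          in_[q] = bidx + c * H * W;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx,
                              IntegerVector in_dims) {
  int H = in_dims[0], W = in_dims[1], C = in_dims[2], N = in_dims[3];
  size_t blk_in = (size_t)H * W * C;
  size_t blk_out = dout.size() / N;
  NumericVector dx(blk_in * N);
  dx.attr("dim") = in_dims;
  for (int n = 0; n < N; ++n) {
    const double* dn = dout.begin() + n * blk_out;
    const int* in_ = idx.begin() + n * blk_out;
    double* xn = dx.begin() + n * blk_in;
    for (size_t q = 0; q < blk_out; ++q) xn[in_[q]] += dn[q];
  }
  return dx;
}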