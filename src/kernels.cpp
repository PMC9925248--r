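// Convolution / pooling kernels for the segmentation network.
//
// Tensor layout follows R arrays: dim (H, W, C, N), column-major, 0-based
// indices in C++. Kernel weights for k x k convolutions arrive flattened from
// an R array of dim (k, k, M, F) as a (k*k*M) x F matrix, so the row index of
// weight element (ki, kj, m) is ki + k*kj + k*k*m. All spatial ops use
// cross-correlation (no kernel flip), stride 1 and "same" zero padding,
// except the stride-2 transposed convolution used for decoder upsampling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  return d;
}

// view of sample n of a (H, W, C, N) tensor as an arma cube (no copy)
static arma::cube sample_cube(NumericVector& x, int H, int W, int C, int n) {
  return arma::cube(x.begin() + (size_t)n * H * W * C, H, W, C, false, true);
}
static arma::cube sample_cube_const(const NumericVector& x, int H, int W, int C, int n) {
  return arma::cube(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                    H, W, C, false, true);
}

// im2col for same-padded, stride-1, dilated k x k convolution.
// col is (H*W) x (k*k*M); column (ki + k*kj + k*k*m) holds channel m shifted
// by (rate*(ki-c), rate*(kj-c)) with zero fill, c = (k-1)/2.
static void im2col(const arma::cube& x, int k, int rate, arma::mat& col) {
  const int H = x.n_rows, W = x.n_cols, M = x.n_slices, c0 = (k - 1) / 2;
  col.zeros(H * W, k * k * M);
  for (int m = 0; m < M; ++m) {
    for (int kj = 0; kj < k; ++kj) {
      const int dj = rate * (kj - c0);
      for (int ki = 0; ki < k; ++ki) {
        const int di = rate * (ki - c0);
        const int ci = ki + k * kj + k * k * m;
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i0 > i1 || j0 > j1) continue;
        for (int j = j0; j <= j1; ++j) {
          const double* src = x.slice_colptr(m, j + dj) + i0 + di;
          double* dst = col.colptr(ci) + (size_t)j * H + i0;
          std::copy(src, src + (i1 - i0 + 1), dst);
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im_acc(const arma::mat& col, int k, int rate, arma::cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, M = gx.n_slices, c0 = (k - 1) / 2;
  for (int m = 0; m < M; ++m) {
    for (int kj = 0; kj < k; ++kj) {
      const int dj = rate * (kj - c0);
      for (int ki = 0; ki < k; ++ki) {
        const int di = rate * (ki - c0);
        const int ci = ki + k * kj + k * k * m;
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i0 > i1 || j0 > j1) continue;
        for (int j = j0; j <= j1; ++j) {
          const double* src = col.colptr(ci) + (size_t)j * H + i0;
          double* dst = gx.slice_colptr(m, j + dj) + i0 + di;
          for (int i = 0; i <= i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, const arma::mat& w, int k, int rate) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3];
  const int F = w.n_cols;
  if ((int)w.n_rows != k * k * M) stop("weight rows != k*k*M");
  NumericVector y((size_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, M, n);
    im2col(xs, k, rate, col);
    arma::mat ym(y.begin() + (size_t)n * H * W * F, H * W, F, false, true);
    ym = col * w;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, const arma::mat& w, NumericVector gy,
                   int k, int rate) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3];
  const int F = w.n_cols;
  NumericVector gx((size_t)H * W * M * N);
  gx.attr("dim") = d;
  arma::mat gw(w.n_rows, F, arma::fill::zeros);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, M, n);
    im2col(xs, k, rate, col);
    arma::mat gym(gy.begin() + (size_t)n * H * W * F, H * W, F, false, true);
    gw += col.t() * gym;
    arma::mat gcol = gym * w.t();
    arma::cube gxs = sample_cube(gx, H, W, M, n);
    col2im_acc(gcol, k, rate, gxs);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// depthwise: w is (k*k) x M, channel m filtered by its own kernel
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, const arma::mat& w, int k, int rate) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3], c0 = (k - 1) / 2;
  if ((int)w.n_rows != k * k || (int)w.n_cols != M) stop("depthwise weight shape");
  NumericVector y((size_t)H * W * M * N);
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, M, n);
    arma::cube ys = sample_cube(y, H, W, M, n);
    for (int m = 0; m < M; ++m) {
      for (int kj = 0; kj < k; ++kj) {
        const int dj = rate * (kj - c0);
        for (int ki = 0; ki < k; ++ki) {
          const int di = rate * (ki - c0);
          const double wv = w(ki + k * kj, m);
          if (wv == 0.0) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
          if (i0 > i1 || j0 > j1) continue;
          ys.slice(m).submat(i0, j0, i1, j1) +=
            wv * xs.slice(m).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, const arma::mat& w, NumericVector gy,
                   int k, int rate) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3], c0 = (k - 1) / 2;
  NumericVector gx((size_t)H * W * M * N);
  gx.attr("dim") = d;
  arma::mat gw(k * k, M, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, M, n);
    arma::cube gys = sample_cube_const(gy, H, W, M, n);
    arma::cube gxs = sample_cube(gx, H, W, M, n);
    for (int m = 0; m < M; ++m) {
      for (int kj = 0; kj < k; ++kj) {
        const int dj = rate * (kj - c0);
        for (int ki = 0; ki < k; ++ki) {
          const int di = rate * (ki - c0);
          const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
          const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
          if (i0 > i1 || j0 > j1) continue;
          const arma::mat gsub = gys.slice(m).submat(i0, j0, i1, j1);
          const arma::mat xsub =
            xs.slice(m).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
          gw(ki + k * kj, m) += arma::accu(gsub % xsub);
          gxs.slice(m).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
            w(ki + k * kj, m) * gsub;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 3x3 stride-2 transposed convolution ("same": output = 2H x 2W).
// y(2i+ki-1, 2j+kj-1, f) += w[ki,kj,m,f] * x(i,j,m); w flattened (9*M) x F.
// [[Rcpp::export]]
NumericVector cpp_tconv_fw(NumericVector x, const arma::mat& w) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3];
  const int F = w.n_cols, Ho = 2 * H, Wo = 2 * W;
  if ((int)w.n_rows != 9 * M) stop("tconv weight rows != 9*M");
  NumericVector y((size_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * M,
                 H * W, M, false, true);
    arma::cube ys = sample_cube(y, Ho, Wo, F, n);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        // weight rows for this tap across channels m: ki + 3*kj + 9*m
        arma::mat wk(M, F);
        for (int m = 0; m < M; ++m) wk.row(m) = w.row(ki + 3 * kj + 9 * m);
        arma::mat z = xm * wk; // (H*W) x F
        for (int f = 0; f < F; ++f) {
          for (int j = 0; j < W; ++j) {
            const int b = 2 * j + kj - 1;
            if (b < 0 || b >= Wo) continue;
            const double* src = z.colptr(f) + (size_t)j * H;
            double* dst = ys.slice_colptr(f, b);
            for (int i = 0; i < H; ++i) {
              const int a = 2 * i + ki - 1;
              if (a < 0 || a >= Ho) continue;
              dst[a] += src[i];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv_bw(NumericVector x, const arma::mat& w, NumericVector gy) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], M = d[2], N = d[3];
  const int F = w.n_cols, Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)H * W * M * N);
  gx.attr("dim") = d;
  arma::mat gw(9 * M, F, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * M,
                 H * W, M, false, true);
    arma::mat gxm(gx.begin() + (size_t)n * H * W * M, H * W, M, false, true);
    arma::cube gys = sample_cube_const(gy, Ho, Wo, F, n);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        arma::mat gk(H * W, F, arma::fill::zeros); // gather gy at this tap
        for (int f = 0; f < F; ++f) {
          for (int j = 0; j < W; ++j) {
            const int b = 2 * j + kj - 1;
            if (b < 0 || b >= Wo) continue;
            const double* src = gys.slice_colptr(f, b);
            double* dst = gk.colptr(f) + (size_t)j * H;
            for (int i = 0; i < H; ++i) {
              const int a = 2 * i + ki - 1;
              if (a < 0 || a >= Ho) continue;
              dst[i] = src[a];
            }
          }
        }
        arma::mat wk(M, F);
        for (int m = 0; m < M; ++m) wk.row(m) = w.row(ki + 3 * kj + 9 * m);
        gxm += gk * wk.t();
        arma::mat gwk = xm.t() * gk; // M x F
        for (int m = 0; m < M; ++m) gw.row(ki + 3 * kj + 9 * m) += gwk.row(m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// 2x2 stride-2 max pooling; argmax kept (1-based linear index per sample
// block) so the backward pass can scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, C, n);
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; int bi = 0, bj = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const double v = xs(2 * i + di, 2 * j + dj, c);
              if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
            }
          y[p] = best;
          idx[p] = (int)((size_t)n * H * W * C + (size_t)c * H * W +
                         (size_t)bj * H + bi) + 1;
          ++p;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// 3x3 stride-1 same max pooling (out-of-range taps ignored)
// [[Rcpp::export]]
List cpp_maxpool3_fw(NumericVector x) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = d;
  IntegerVector idx((size_t)H * W * C * N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube_const(x, H, W, C, n);
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double best = -1e300; int bi = i, bj = j;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= H) continue;
              const double v = xs(ii, jj, c);
              if (v > best) { best = v; bi = ii; bj = jj; }
            }
          }
          y[p] = best;
          idx[p] = (int)((size_t)n * H * W * C + (size_t)c * H * W +
                         (size_t)bj * H + bi) + 1;
          ++p;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// shared backward for both poolings: scatter-add grads to stored argmax
// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector idx,
                             IntegerVector xdim) {
  const size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < gy.size(); ++p) gx[idx[p] - 1] += gy[p];
  return gx;
}
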