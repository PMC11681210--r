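// Compiled kernels for the network engine: same-padded (dilated) 2-D
// convolution, 2x2 stride-2 transpose convolution, max pooling, and the
// median filter used in preprocessing. Tensors are R arrays in
// (height, width, channel, sample) order, column-major.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Training repeatedly allocates and frees multi-megabyte tensors; with
// glibc defaults those round-trip through mmap/munmap and the page faults
// dominate wall time. Keep large freed blocks in the arena instead.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}

// Fill A ((H*W) x (KH*KW*C)) with im2col patches of one sample,
// zero-padded so output size equals input size. Row index p = h + H*w,
// column index q = kh + KH*(kw + KW*c): the same flattening order as an
// R array of dim (KH, KW, C, F), so the kernel reshapes to a
// (KH*KW*C) x F matrix with no copying.
static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int dil, arma::mat& A) {
  const int ch = (KH - 1) / 2, cw = (KW - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      const int dw = (kw - cw) * dil;
      for (int kh = 0; kh < KH; ++kh) {
        const int dh = (kh - ch) * dil;
        double* Acol = A.colptr(kh + KH * (kw + KW * c));
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          double* Ap = Acol + (std::size_t)H * w;
          if (iw < 0 || iw >= W) { std::fill(Ap, Ap + H, 0.0); continue; }
          const double* xcw = xc + (std::size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh;
            Ap[h] = (ih >= 0 && ih < H) ? xcw[ih] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of dA (same layout as im2col output) back onto dx.
static void col2im_add(const arma::mat& dA, int H, int W, int C,
                       int KH, int KW, int dil, double* dx) {
  const int ch = (KH - 1) / 2, cw = (KW - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      const int dw = (kw - cw) * dil;
      for (int kh = 0; kh < KH; ++kh) {
        const int dh = (kh - ch) * dil;
        const double* Acol = dA.colptr(kh + KH * (kw + KW * c));
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw;
          if (iw < 0 || iw >= W) continue;
          const double* Ap = Acol + (std::size_t)H * w;
          double* xcw = xc + (std::size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            const int ih = h + dh;
            if (ih >= 0 && ih < H) xcw[ih] += Ap[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  if (wd[2] != C) stop("kernel channel count does not match input");
  arma::mat Wm(w.begin(), (std::size_t)KH * KW * C, F, false, true);
  NumericVector y((R_xlen_t)(H)*( W)*( F)*( N));
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  const bool one_by_one = (KH == 1 && KW == 1);
  arma::mat A;
  if (!one_by_one) A.set_size(H * W, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (std::size_t)H * W * F * n, H * W, F, false, true);
    if (one_by_one) {
      // a 1x1 conv is a plain matrix product on the (H*W, C) view
      const arma::mat X(const_cast<double*>(x.begin()) +
                        (std::size_t)H * W * C * n, H * W, C, false, true);
      Y = X * Wm;
    } else {
      im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, KH, KW, dil, A);
      Y = A * Wm;
    }
    for (int f = 0; f < F; ++f) Y.col(f) += b[f];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  arma::mat Wm(w.begin(), (std::size_t)KH * KW * C, F, false, true);
  NumericVector dx((R_xlen_t)(H)*( W)*( C)*( N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)(KH)*( KW)*( C)*( F));
  dw.attr("dim") = IntegerVector::create(KH, KW, C, F);
  NumericVector db(F);
  arma::mat dWm(dw.begin(), (std::size_t)KH * KW * C, F, false, true);
  const bool one_by_one = (KH == 1 && KW == 1);
  arma::mat A, dA;
  if (!one_by_one) {
    A.set_size(H * W, KH * KW * C);
    if (need_dx) dA.set_size(H * W, KH * KW * C);
  }
  for (int n = 0; n < N; ++n) {
    arma::mat dY(dy.begin() + (std::size_t)H * W * F * n, H * W, F, false, true);
    for (int f = 0; f < F; ++f) db[f] += arma::accu(dY.col(f));
    if (one_by_one) {
      const arma::mat X(const_cast<double*>(x.begin()) +
                        (std::size_t)H * W * C * n, H * W, C, false, true);
      dWm += X.t() * dY;
      if (need_dx) {
        arma::mat dX(dx.begin() + (std::size_t)H * W * C * n, H * W, C,
                     false, true);
        dX += dY * Wm.t();
      }
    } else {
      im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, KH, KW, dil, A);
      dWm += A.t() * dY;
      if (need_dx) {
        dA = dY * Wm.t();
        col2im_add(dA, H, W, C, KH, KW, dil,
                   dx.begin() + (std::size_t)H * W * C * n);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transpose convolution, kernel 2x2, stride 2: each input pixel paints a
// disjoint 2x2 output patch, doubling the spatial size.
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], F = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C)
    stop("transpose-conv kernel must be (2, 2, C_in, F)");
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((R_xlen_t)(H2)*( W2)*( F)*( N));
  y.attr("dim") = IntegerVector::create(H2, W2, F, N);
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (std::size_t)H2 * W2 * F * n;
    const double* xn = x.begin() + (std::size_t)H * W * C * n;
    for (int f = 0; f < F; ++f) {
      double* yf = yn + (std::size_t)H2 * W2 * f;
      std::fill(yf, yf + (std::size_t)H2 * W2, b[f]);
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (std::size_t)H * W * c;
        const double* wk = w.begin() + 4 * (c + (std::size_t)C * f);
        for (int j = 0; j < W; ++j) {
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + (std::size_t)H * j];
            double* base = yf + (2 * i) + (std::size_t)H2 * (2 * j);
            base[0]      += v * wk[0];
            base[1]      += v * wk[1];
            base[H2]     += v * wk[2];
            base[H2 + 1] += v * wk[3];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], F = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx((R_xlen_t)(H)*( W)*( C)*( N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)(2)*( 2)*( C)*( F));
  dw.attr("dim") = IntegerVector::create(2, 2, C, F);
  NumericVector db(F);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (std::size_t)H2 * W2 * F * n;
    const double* xn = x.begin() + (std::size_t)H * W * C * n;
    double* dxn = dx.begin() + (std::size_t)H * W * C * n;
    for (int f = 0; f < F; ++f) {
      const double* gf = dyn + (std::size_t)H2 * W2 * f;
      double acc = 0.0;
      for (std::size_t k = 0; k < (std::size_t)H2 * W2; ++k) acc += gf[k];
      db[f] += acc;
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (std::size_t)H * W * c;
        double* dxc = dxn + (std::size_t)H * W * c;
        const double* wk = w.begin() + 4 * (c + (std::size_t)C * f);
        double* dwk = dw.begin() + 4 * (c + (std::size_t)C * f);
        for (int j = 0; j < W; ++j) {
          for (int i = 0; i < H; ++i) {
            const double* g = gf + (2 * i) + (std::size_t)H2 * (2 * j);
            const double v = xc[i + (std::size_t)H * j];
            dwk[0] += v * g[0];
            dwk[1] += v * g[1];
            dwk[2] += v * g[H2];
            dwk[3] += v * g[H2 + 1];
            dxc[i + (std::size_t)H * j] +=
              wk[0] * g[0] + wk[1] * g[1] + wk[2] * g[H2] + wk[3] * g[H2 + 1];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling; idx records the 0-based flat argmax for the
// backward scatter. Requires even H and W.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("2x2 max pooling needs even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)(Ho)*( Wo)*( C)*( N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)(Ho)*( Wo)*( C)*( N));
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)H * W * (c + (std::size_t)C * n);
      const std::size_t ooff = (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          std::size_t best = off + (2 * i) + (std::size_t)H * (2 * j);
          double bv = xp[best];
          const std::size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          y[ooff + i + (std::size_t)Ho * j] = bv;
          idx[ooff + i + (std::size_t)Ho * j] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  NumericVector dx((R_xlen_t)(xdim[0])*( xdim[1])*( xdim[2])*( xdim[3]));
  dx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t k = 0; k < idx.size(); ++k) dx[idx[k]] += dy[k];
  return dx;
}

// 3x3 stride-1 max pooling with same padding (border maxima taken over the
// in-bounds neighbourhood only).
// [[Rcpp::export]]
List cpp_maxpool3_same_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)(H)*( W)*( C)*( N));
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  IntegerVector idx((R_xlen_t)(H)*( W)*( C)*( N));
  idx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          std::size_t best = 0;
          double bv = -std::numeric_limits<double>::infinity();
          for (int dj = std::max(0, j - 1); dj <= std::min(W - 1, j + 1); ++dj)
            for (int di = std::max(0, i - 1); di <= std::min(H - 1, i + 1); ++di) {
              const std::size_t p = off + di + (std::size_t)H * dj;
              if (xp[p] > bv) { bv = xp[p]; best = p; }
            }
          y[off + i + (std::size_t)H * j] = bv;
          idx[off + i + (std::size_t)H * j] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_same_bwd(IntegerVector idx, NumericVector dy,
                                    IntegerVector xdim) {
  NumericVector dx((R_xlen_t)(xdim[0])*( xdim[1])*( xdim[2])*( xdim[3]));
  dx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t k = 0; k < idx.size(); ++k) dx[idx[k]] += dy[k];
  return dx;
}

// k x k median filter with replicate (edge-clamped) padding.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("median kernel must be a positive odd integer");
  const int H = x.nrow(), W = x.ncol(), r = k / 2;
  NumericMatrix y(H, W);
  std::vector<double> buf((std::size_t)k * k);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      std::size_t m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = std::min(W - 1, std::max(0, j + dj));
        for (int di = -r; di <= r; ++di) {
          const int ii = std::min(H - 1, std::max(0, i + di));
          buf[m++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      y(i, j) = buf[m / 2];
    }
  return y;
}
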