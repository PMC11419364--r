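// Core dense tensor primitives for the CPU training engine.
// Layout convention (R column-major): feature maps are (H, W, C, N),
// convolution weights are (k, k, Cin/groups, Cout). im2col column index
// r = kh + k*kw + k*k*ci matches the flattened weight layout, so each
// group's convolution is a single GEMM.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// build im2col matrix for one sample and one channel group
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad,
                   int c0, int cg, int Ho, int Wo, arma::mat& col) {
  // col is (k*k*cg) x (Ho*Wo)
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int pos = oh + Ho * ow;
      double* dst = col.colptr(pos);
      for (int ci = 0; ci < cg; ++ci) {
        const double* xc = x + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            const int r = kh + k * kw + k * k * ci;
            dst[r] = (ih >= 0 && ih < H && iw >= 0 && iw < W)
                       ? xc[ih + (size_t)H * iw] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-accumulate a column matrix back into an image gradient
static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int k, int stride, int pad,
                   int c0, int cg, int Ho, int Wo) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int pos = oh + Ho * ow;
      const double* src = col.colptr(pos);
      for (int ci = 0; ci < cg; ++ci) {
        double* xc = dx + (size_t)(c0 + ci) * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)H * iw] += src[kh + k * kw + k * k * ci];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int stride, int pad, int groups) {
  int xd[4]; get_dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernels unsupported");
  if (C / groups != cg || C % groups != 0 || Cout % groups != 0)
    stop("channel/group mismatch");
  const int cog = Cout / groups;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output would be empty");

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wmat(const_cast<double*>(w.begin()),
                       (size_t)k * k * cg, Cout, false, true);
  arma::mat col((size_t)k * k * cg, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, C, k, stride, pad, g * cg, cg, Ho, Wo, col);
      arma::mat Wg = Wmat.cols(g * cog, (g + 1) * cog - 1);
      arma::mat out = col.t() * Wg;  // (Ho*Wo) x cog
      std::copy(out.begin(), out.end(), yn + (size_t)g * cog * Ho * Wo);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int groups) {
  int xd[4]; get_dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], cg = wd[2], Cout = wd[3];
  const int cog = Cout / groups;
  int yd[4]; get_dims4(dy, yd);
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");

  const arma::mat Wmat(const_cast<double*>(w.begin()),
                       (size_t)k * k * cg, Cout, false, true);
  arma::mat dWmat(dw.begin(), (size_t)k * k * cg, Cout, false, true);
  arma::mat col((size_t)k * k * cg, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, C, k, stride, pad, g * cg, cg, Ho, Wo, col);
      const arma::mat dYg(const_cast<double*>(dyn) + (size_t)g * cog * Ho * Wo,
                          (size_t)Ho * Wo, cog, false, true);
      dWmat.cols(g * cog, (g + 1) * cog - 1) += col * dYg;
      arma::mat Wg = Wmat.cols(g * cog, (g + 1) * cog - 1);
      arma::mat dcol = Wg * dYg.t();  // (k*k*cg) x (Ho*Wo)
      col2im(dcol, dxn, H, W, C, k, stride, pad, g * cg, cg, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int xd[4]; get_dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output would be empty");
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 1-based flat index into x, NA if none
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf; long bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const double v = xc[ih + (size_t)H * iw];
              if (v > best) { best = v; bi = ih + (size_t)H * iw; }
            }
          }
          // y is (Ho, Wo, C, N); we iterate oh fastest within (ow, c, n)
          const size_t yi = (size_t)oh + Ho * ((size_t)ow + Wo * ((size_t)c + (size_t)C * n));
          y[yi] = (bi >= 0) ? best : 0.0;
          idx[yi] = (bi >= 0) ? (int)(base + bi + 1) : NA_INTEGER;
          (void)o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  const size_t ny = dy.size();
  for (size_t i = 0; i < ny; ++i) {
    const int j = idx[i];
    if (j != NA_INTEGER) dx[j - 1] += dy[i];
  }
  return dx;
}
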