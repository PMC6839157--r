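// Low-level layer kernels for the CNN engine.
//
// Tensor layout follows R arrays: (H, W, C, N), column-major, H fastest.
// Convolutions use im2col + GEMM, batched over the whole mini-batch so
// BLAS sees one well-shaped multiplication per layer; transposed
// convolutions reuse the same machinery through the conv/deconv duality
// (deconv forward == conv backward-data of the mirrored convolution).
// The patch matrix is colsT: (N*Ho*Wo) x (k*k*C), row j = ho + Ho*wo +
// HoWo*n, column r = kh + k*kw + k*k*c, so inner loops walk contiguous
// memory. Forward can hand colsT back to the caller so backward skips
// re-extraction.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

// fill rows [rowOff, rowOff + Ho*Wo) of colsT from one image, writing
// padding zeros inline (colsT need not be pre-zeroed)
static void im2colT(const double* x, int H, int W, int C,
                    int k, int s, int p, int Ho, int Wo,
                    arma::mat& colsT, size_t rowOff) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        double* col = colsT.colptr(r) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          double* dst = col + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          int ho0 = 0, hi = -p + kh;
          while (hi < 0) { hi += s; ++ho0; }
          int ho1 = ho0;
          // advance ho1 to first index with hi out of range
          ho1 = ho0 + (H - 1 - hi) / s + 1;
          if (ho1 > Ho) ho1 = Ho;
          std::fill(dst, dst + ho0, 0.0);
          if (s == 1) {
            std::copy(xcol + hi, xcol + hi + (ho1 - ho0), dst + ho0);
          } else {
            for (int ho = ho0; ho < ho1; ++ho, hi += s) dst[ho] = xcol[hi];
          }
          std::fill(dst + ho1, dst + Ho, 0.0);
        }
      }
  }
}

// accumulate transpose of im2colT for one image (row block rowOff)
static void col2imT(const arma::mat& colsT, int H, int W, int C,
                    int k, int s, int p, int Ho, int Wo,
                    double* x, size_t rowOff) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        const double* col = colsT.colptr(r) + rowOff;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* src = col + (size_t)Ho * wo;
          int ho = 0, hi = -p + kh;
          while (hi < 0) { hi += s; ++ho; }
          for (; ho < Ho && hi < H; ++ho, hi += s) xcol[hi] += src[ho];
        }
      }
  }
}

static IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// gather (H,W,C,N) image blocks into an (N*HW x C) matrix
static void gather_rows(const double* x, int HW, int C, int N, arma::mat& Xb) {
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::copy(x + (size_t)HW * (c + (size_t)C * n),
                x + (size_t)HW * (c + (size_t)C * n) + HW,
                Xb.colptr(c) + (size_t)HW * n);
}

// scatter an (N*HW x C) matrix back into (H,W,C,N) layout, adding bias
static void scatter_rows(const arma::mat& Yb, int HW, int C, int N,
                         const double* bias, double* y) {
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = Yb.colptr(c) + (size_t)HW * n;
      double* dst = y + (size_t)HW * (c + (size_t)C * n);
      if (bias) {
        const double b = bias[c];
        for (int i = 0; i < HW; ++i) dst[i] = src[i] + b;
      } else {
        std::copy(src, src + HW, dst);
      }
    }
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                  int stride, int pad, bool keepCols = false) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const size_t HoWo = (size_t)Ho * Wo;
  NumericVector y(HoWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat* cp = new arma::mat(HoWo * N, k * k * Cin);
  for (int n = 0; n < N; ++n)
    im2colT(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
            Ho, Wo, *cp, HoWo * n);
  arma::mat Yb = (*cp) * Wm;
  scatter_rows(Yb, (int)HoWo, Cout, N, b.begin(), y.begin());
  if (keepCols) {
    XPtr<arma::mat> colsPtr(cp, true);
    return List::create(_["y"] = y, _["cols"] = colsPtr);
  }
  delete cp;
  return List::create(_["y"] = y);
}

// `cols` may be the cached patch matrix from the forward pass (an
// external pointer); pass R NULL to re-extract from x.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, SEXP cols) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const size_t HoWo = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false, true);

  arma::mat* colsT;
  std::unique_ptr<arma::mat> own;
  if (cols != R_NilValue) {
    colsT = XPtr<arma::mat>(cols).get();
  } else {
    own.reset(new arma::mat(HoWo * N, k * k * Cin));
    for (int n = 0; n < N; ++n)
      im2colT(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad,
              Ho, Wo, *own, HoWo * n);
    colsT = own.get();
  }
  arma::mat Dyb(HoWo * N, Cout);
  gather_rows(dy.begin(), (int)HoWo, Cout, N, Dyb);
  dWm = colsT->t() * Dyb;
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(Dyb.col(co));
  arma::mat dcolsT = Dyb * Wm.t();
  for (int n = 0; n < N; ++n)
    col2imT(dcolsT, H, W, C, k, stride, pad, Ho, Wo,
            dx.begin() + (size_t)H * W * C * n, HoWo * n);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Build V (k*k*Cout x Cin) from w (k,k,Cin,Cout): v(kh,kw,co,ci) = w(kh,kw,ci,co)
static arma::mat mirror_weights(const NumericVector& w, int k, int Cin, int Cout) {
  arma::mat Vm(k * k * Cout, Cin);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Vm(kh + k * kw + k * k * co, ci) =
            wp[kh + k * (kw + k * (ci + (size_t)Cin * co))];
  return Vm;
}

// transposed convolution: output side = (in-1)*stride - 2*pad + k
// [[Rcpp::export]]
NumericVector cpp_deconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("deconv: channel mismatch");
  const int H2 = (H - 1) * stride - 2 * pad + k;
  const int W2 = (W - 1) * stride - 2 * pad + k;
  const size_t HW = (size_t)H * W;
  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  arma::mat Vm = mirror_weights(w, k, Cin, Cout);
  arma::mat Xb(HW * N, C);
  gather_rows(x.begin(), (int)HW, C, N, Xb);
  arma::mat dcolsT = Xb * Vm.t();  // (N*HW) x (k*k*Cout)
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)H2 * W2 * Cout * n;
    col2imT(dcolsT, H2, W2, Cout, k, stride, pad, H, W, yn, HW * n);
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)H2 * W2 * co;
      for (size_t i = 0; i < (size_t)H2 * W2; ++i) yc[i] += b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int H2 = yd[0], W2 = yd[1];
  const size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Vm = mirror_weights(w, k, Cin, Cout);
  arma::mat colsT(HW * N, k * k * Cout);
  for (int n = 0; n < N; ++n)
    im2colT(dy.begin() + (size_t)H2 * W2 * Cout * n, H2, W2, Cout,
            k, stride, pad, H, W, colsT, HW * n);
  arma::mat dXb = colsT * Vm;            // (N*HW) x Cin
  scatter_rows(dXb, (int)HW, C, N, nullptr, dx.begin());
  arma::mat Xb(HW * N, C);
  gather_rows(x.begin(), (int)HW, C, N, Xb);
  arma::mat dVm = colsT.t() * Xb;        // (k*k*Cout) x Cin
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)H2 * W2 * co;
      double acc = 0.0;
      for (size_t i = 0; i < (size_t)H2 * W2; ++i) acc += dyc[i];
      db[co] += acc;
    }
  }
  // permute dVm back into (k,k,Cin,Cout)
  double* dwp = dw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          dwp[kh + k * (kw + k * (ci + (size_t)Cin * co))] =
            dVm(kh + k * kw + k * k * co, ci);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling. stride 2: halves H and W (H, W even). stride 1:
// size-preserving with implicit -Inf padding at the bottom/right edge.
// idx holds 0-based offsets into x of each selected maximum (first-wins ties).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int stride) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (stride == 2) ? H / 2 : H;
  const int Wo = (stride == 2) ? W / 2 : W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride, w0 = wo * stride;
          double best = -HUGE_VAL;
          size_t besti = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2) {
            const int wi = w0 + dw2;
            if (wi >= W) continue;
            for (int dh = 0; dh < 2; ++dh) {
              const int hi = h0 + dh;
              if (hi >= H) continue;
              const size_t xi = base + hi + (size_t)H * wi;
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          const size_t oi = obase + ho + (size_t)Ho * wo;
          yp[oi] = best;
          ip[oi] = (int)besti;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  size_t len = 1;
  for (int i = 0; i < xdim.size(); ++i) len *= (size_t)xdim[i];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const size_t m = (size_t)dy.size();
  for (size_t i = 0; i < m; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// batchnorm over (H, W, N) per channel, training mode (batch statistics)
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mean(C), invstd(C), var(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = mu; var[c] = v; invstd[c] = is;
    const double a = gamma[c] * is, b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      double* yc = yp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                           NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / std::sqrt(rvar[c] + eps);
    const double b0 = beta[c] - a * rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      double* yc = yp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector invstd, NumericVector dy) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const double* dyc = dyp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        sdy += dyc[i];
        sdyx += dyc[i] * (xc[i] - mu) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c] * is / m;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const double* dyc = dyp + HW * (c + (size_t)C * n);
      double* dxc = dxp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xc[i] - mu) * is;
        dxc[i] = g * (m * dyc[i] - sdy - xhat * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = (size_t)x.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t n = (size_t)x.size();
  for (size_t i = 0; i < n; ++i) dxp[i] = xp[i] > 0 ? dyp[i] : 0.0;
  return dx;
}
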