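// Direct (no-im2col) convolution kernels. On layout [H,W,C,N] a k x k
// convolution is a sum of k*k*C shifted AXPY passes per output channel;
// activations at training scale live in cache, so this avoids the k*k
// memory blow-up of im2col. 1x1 convolutions run as one GEMM per sample
// on contiguous (H*W x C) views.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

static void gemm(char ta, char tb, int m, int n, int kk, double alpha,
                 const double* A, int lda, const double* B, int ldb,
                 double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector conv_fwd_direct(NumericVector x, NumericMatrix Wm, NumericVector b,
                       int H, int W, int C, int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Co = Wm.ncol();
  NumericVector y((size_t)Ho * Wo * Co * N);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = Wm.begin();
  size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  if (k == 1 && stride == 1) {
    for (int n = 0; n < N; ++n)
      gemm('N', 'N', HW, Co, C, 1.0, xp + HW * C * n, HW, wp, C, 0.0,
           yp + HW * Co * n, HW);
  } else {
    int K = k * k * C;
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Co; ++co) {
        double* yc = yp + HWo * (co + (size_t)Co * n);
        const double* wcol = wp + (size_t)K * co;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + HW * (c + (size_t)C * n);
          for (int dw = 0; dw < k; ++dw)
            for (int dh = 0; dh < k; ++dh) {
              double wv = wcol[dh + k * dw + k * k * c];
              if (wv == 0.0) continue;
              for (int wo = 0; wo < Wo; ++wo) {
                int w = wo * stride + dw - pad;
                if (w < 0 || w >= W) continue;
                double* ycol = yc + (size_t)Ho * wo;
                const double* xcol = xc + (size_t)H * w;
                int ho0 = 0, ho1 = Ho;
                while (ho0 < Ho && ho0 * stride + dh - pad < 0) ++ho0;
                while (ho1 > ho0 && (ho1 - 1) * stride + dh - pad >= H) --ho1;
                const double* xs = xcol + (ho0 * stride + dh - pad);
                if (stride == 1)
                  for (int ho = ho0; ho < ho1; ++ho)
                    ycol[ho] += wv * xs[ho - ho0];
                else
                  for (int ho = ho0; ho < ho1; ++ho)
                    ycol[ho] += wv * xs[(size_t)(ho - ho0) * stride];
              }
            }
        }
      }
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double bv = b[co];
      double* yc = yp + HWo * (co + (size_t)Co * n);
      for (size_t i = 0; i < HWo; ++i) yc[i] += bv;
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List conv_bwd_direct(NumericVector x, NumericMatrix Wm, NumericVector dy,
              int H, int W, int C, int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Co = Wm.ncol();
  int K = k * k * C;
  NumericVector dx((size_t)H * W * C * N);
  NumericMatrix dW(K, Co);
  NumericVector db(Co);
  const double* xp = x.begin();
  const double* dp = dy.begin();
  const double* wp = Wm.begin();
  double* dxp = dx.begin();
  double* dWp = dW.begin();
  size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* dc = dp + HWo * (co + (size_t)Co * n);
      double s = 0.0;
      for (size_t i = 0; i < HWo; ++i) s += dc[i];
      db[co] += s;
    }
  if (k == 1 && stride == 1) {
    for (int n = 0; n < N; ++n) {
      const double* xn = xp + HW * C * n;
      const double* dn = dp + HW * Co * n;
      gemm('T', 'N', C, Co, HW, 1.0, xn, HW, dn, HW, 1.0, dWp, C);
      gemm('N', 'T', HW, C, Co, 1.0, dn, HW, wp, C, 0.0, dxp + HW * C * n, HW);
    }
    // dW accumulated in (C x Co) order equals the (1*1*C x Co) layout
  } else {
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Co; ++co) {
        const double* dc = dp + HWo * (co + (size_t)Co * n);
        const double* wcol = wp + (size_t)K * co;
        double* dWcol = dWp + (size_t)K * co;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + HW * (c + (size_t)C * n);
          double* dxc = dxp + HW * (c + (size_t)C * n);
          for (int dw = 0; dw < k; ++dw)
            for (int dh = 0; dh < k; ++dh) {
              double wv = wcol[dh + k * dw + k * k * c];
              double acc = 0.0;
              for (int wo = 0; wo < Wo; ++wo) {
                int w = wo * stride + dw - pad;
                if (w < 0 || w >= W) continue;
                const double* dcol = dc + (size_t)Ho * wo;
                const double* xcol = xc + (size_t)H * w;
                double* dxcol = dxc + (size_t)H * w;
                int ho0 = 0, ho1 = Ho;
                while (ho0 < Ho && ho0 * stride + dh - pad < 0) ++ho0;
                while (ho1 > ho0 && (ho1 - 1) * stride + dh - pad >= H) --ho1;
                int off = ho0 * stride + dh - pad;
                if (stride == 1) {
                  for (int ho = ho0; ho < ho1; ++ho) {
                    double dv = dcol[ho];
                    acc += dv * xcol[off + ho - ho0];
                    dxcol[off + ho - ho0] += wv * dv;
                  }
                } else {
                  for (int ho = ho0; ho < ho1; ++ho) {
                    double dv = dcol[ho];
                    size_t xi = off + (size_t)(ho - ho0) * stride;
                    acc += dv * xcol[xi];
                    dxcol[xi] += wv * dv;
                  }
                }
              }
              dWcol[dh + k * dw + k * k * c] += acc;
            }
        }
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
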