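// Fused convolution kernels: im2col into reusable scratch buffers plus
// direct BLAS dgemm, so a training step allocates only its outputs.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

static std::vector<double> g_cols, g_mat, g_cols2;
// (3x3 convolutions live in conv_direct.cpp; scratch buffers serve convT2)

static void im2col_into(const double* x, int H, int W, int C, int N,
                        int k, int stride, int pad, double* out, int R) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        double* ocol = out + (size_t)col * R;
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            int w = wo * stride + dw - pad;
            size_t rbase = (size_t)Ho * (wo + (size_t)Wo * n);
            if (w < 0 || w >= W) {
              std::fill(ocol + rbase, ocol + rbase + Ho, 0.0);
              continue;
            }
            const double* xcw = xc + (size_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * stride + dh - pad;
              ocol[rbase + ho] = (h < 0 || h >= H) ? 0.0 : xcw[h];
            }
          }
        }
      }
}

static void col2im_acc(const double* d, int H, int W, int C, int N,
                       int k, int stride, int pad, double* x, int R) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        const double* dcol = d + (size_t)col * R;
        for (int n = 0; n < N; ++n) {
          double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            int w = wo * stride + dw - pad;
            if (w < 0 || w >= W) continue;
            size_t rbase = (size_t)Ho * (wo + (size_t)Wo * n);
            double* xcw = xc + (size_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              int h = ho * stride + dh - pad;
              if (h >= 0 && h < H) xcw[h] += dcol[rbase + ho];
            }
          }
        }
      }
}

// [H,W,C,N] -> rows (h,w,n) x C
static void feat2mat_into(const double* x, int H, int W, int C, int N,
                          double* out) {
  size_t R = (size_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    double* ocol = out + (size_t)c * R;
    for (int n = 0; n < N; ++n)
      std::copy(x + (size_t)H * W * (c + (size_t)C * n),
                x + (size_t)H * W * (c + 1 + (size_t)C * n),
                ocol + (size_t)H * W * n);
  }
}

static void mat2feat_into(const double* m, int H, int W, int C, int N,
                          double* x) {
  size_t R = (size_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    const double* mcol = m + (size_t)c * R;
    for (int n = 0; n < N; ++n)
      std::copy(mcol + (size_t)H * W * n, mcol + (size_t)H * W * (n + 1),
                x + (size_t)H * W * (c + (size_t)C * n));
  }
}

static void gemm(char ta, char tb, int m, int n, int kk, const double* A,
                 int lda, const double* B, int ldb, double beta, double* C,
                 int ldc) {
  double one = 1.0;
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &one, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector conv_fwd_gemm(NumericVector x, NumericMatrix Wm, NumericVector b,
                            int H, int W, int C, int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = Ho * Wo * N, K = k * k * C, Co = Wm.ncol();
  NumericVector y((size_t)Ho * Wo * Co * N);
  if (k == 1 && stride == 1) {
    g_cols.resize((size_t)R * C);
    feat2mat_into(x.begin(), H, W, C, N, g_cols.data());
  } else {
    g_cols.resize((size_t)R * K);
    im2col_into(x.begin(), H, W, C, N, k, stride, pad, g_cols.data(), R);
  }
  g_mat.resize((size_t)R * Co);
  gemm('N', 'N', R, Co, K, g_cols.data(), R, Wm.begin(), K, 0.0, g_mat.data(), R);
  for (int co = 0; co < Co; ++co) {
    double bv = b[co];
    double* m = g_mat.data() + (size_t)co * R;
    for (int i = 0; i < R; ++i) m[i] += bv;
  }
  mat2feat_into(g_mat.data(), Ho, Wo, Co, N, y.begin());
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List conv_bwd_gemm(NumericVector x, NumericMatrix Wm, NumericVector dy,
                   int H, int W, int C, int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = Ho * Wo * N, K = k * k * C, Co = Wm.ncol();
  NumericVector dx((size_t)H * W * C * N);
  NumericMatrix dW(K, Co);
  NumericVector db(Co);
  g_cols.resize((size_t)R * K);
  if (k == 1 && stride == 1) feat2mat_into(x.begin(), H, W, C, N, g_cols.data());
  else im2col_into(x.begin(), H, W, C, N, k, stride, pad, g_cols.data(), R);
  g_mat.resize((size_t)R * Co);
  feat2mat_into(dy.begin(), Ho, Wo, Co, N, g_mat.data());
  gemm('T', 'N', K, Co, R, g_cols.data(), R, g_mat.data(), R, 0.0, dW.begin(), K);
  for (int co = 0; co < Co; ++co) {
    const double* m = g_mat.data() + (size_t)co * R;
    double s = 0.0;
    for (int i = 0; i < R; ++i) s += m[i];
    db[co] = s;
  }
  g_cols2.resize((size_t)R * K);
  gemm('N', 'T', R, K, Co, g_mat.data(), R, Wm.begin(), K, 0.0, g_cols2.data(), R);
  if (k == 1 && stride == 1) mat2feat_into(g_cols2.data(), H, W, C, N, dx.begin());
  else col2im_acc(g_cols2.data(), H, W, C, N, k, stride, pad, dx.begin(), R);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector convT2_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                         int H, int W, int C, int N) {
  int R = H * W * N, Co = Wm.ncol() / 4;
  NumericVector y((size_t)4 * H * W * Co * N);
  g_cols.resize((size_t)R * C);
  feat2mat_into(x.begin(), H, W, C, N, g_cols.data());
  g_mat.resize((size_t)R * 4 * Co);
  gemm('N', 'N', R, 4 * Co, C, g_cols.data(), R, Wm.begin(), C, 0.0,
       g_mat.data(), R);
  int H2 = 2 * H, W2 = 2 * W;
  double* yp = y.begin();
  for (int co = 0; co < Co; ++co)
    for (int dw = 0; dw < 2; ++dw)
      for (int dh = 0; dh < 2; ++dh) {
        const double* mcol = g_mat.data() + (size_t)(dh + 2 * dw + 4 * co) * R;
        for (int n = 0; n < N; ++n) {
          double* yc = yp + (size_t)H2 * W2 * (co + (size_t)Co * n);
          const double* md = mcol + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            double* ycw = yc + (size_t)H2 * (2 * w + dw) + dh;
            const double* mw = md + (size_t)H * w;
            for (int h = 0; h < H; ++h) ycw[2 * h] = mw[h] + b[co];
          }
        }
      }
  y.attr("dim") = IntegerVector::create(H2, W2, Co, N);
  return y;
}

// [[Rcpp::export]]
List convT2_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy,
                int H, int W, int C, int N) {
  int R = H * W * N, Co = Wm.ncol() / 4;
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  NumericMatrix dW(C, 4 * Co);
  NumericVector db(Co);
  // gather dy into mat layout (R x 4Co) and accumulate bias grads
  g_mat.resize((size_t)R * 4 * Co);
  const double* dp = dy.begin();
  for (int co = 0; co < Co; ++co) {
    double s = 0.0;
    for (int dw = 0; dw < 2; ++dw)
      for (int dh = 0; dh < 2; ++dh) {
        double* mcol = g_mat.data() + (size_t)(dh + 2 * dw + 4 * co) * R;
        for (int n = 0; n < N; ++n) {
          const double* yc = dp + (size_t)H2 * W2 * (co + (size_t)Co * n);
          double* md = mcol + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const double* ycw = yc + (size_t)H2 * (2 * w + dw) + dh;
            double* mw = md + (size_t)H * w;
            for (int h = 0; h < H; ++h) {
              mw[h] = ycw[2 * h];
              s += ycw[2 * h];
            }
          }
        }
      }
    db[co] = s;
  }
  g_cols.resize((size_t)R * C);
  feat2mat_into(x.begin(), H, W, C, N, g_cols.data());
  gemm('T', 'N', C, 4 * Co, R, g_cols.data(), R, g_mat.data(), R, 0.0,
       dW.begin(), C);
  g_cols2.resize((size_t)R * C);
  gemm('N', 'T', R, C, 4 * Co, g_mat.data(), R, Wm.begin(), C, 0.0,
       g_cols2.data(), R);
  mat2feat_into(g_cols2.data(), H, W, C, N, dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
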