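#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major arrays [H, W, C, N] (H fastest).
// im2col rows are ordered (h, w, n) with h fastest; columns are ordered
// (dh, dw, c) with dh fastest, matching the (k*k*Cin) x Cout weight layout.

// [[Rcpp::export]]
NumericMatrix im2col_hwcn(NumericVector x, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = Ho * Wo * N;
  NumericMatrix out(R, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        double* ocol = op + (size_t)col * R;
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            int w = wo * stride + dw - pad;
            size_t rbase = (size_t)Ho * (wo + (size_t)Wo * n);
            if (w < 0 || w >= W) {
              for (int ho = 0; ho < Ho; ++ho) ocol[rbase + ho] = 0.0;
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
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_hwcn(NumericMatrix d, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = Ho * Wo * N;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* dp = d.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        const double* dcol = dp + (size_t)col * R;
        for (int n = 0; n < N; ++n) {
          double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
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
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// [H,W,C,N] -> (H*W*N) x C matrix, rows ordered (h, w, n)
// [[Rcpp::export]]
NumericMatrix feat_to_mat(NumericVector x, int H, int W, int C, int N) {
  int R = H * W * N;
  NumericMatrix out(R, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    double* ocol = op + (size_t)c * R;
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* od = ocol + (size_t)H * W * n;
      std::copy(xc, xc + (size_t)H * W, od);
    }
  }
  return out;
}

// inverse of feat_to_mat
// [[Rcpp::export]]
NumericVector mat_to_feat(NumericMatrix m, int H, int W, int C, int N) {
  int R = H * W * N;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* mp = m.begin();
  for (int c = 0; c < C; ++c) {
    const double* mcol = mp + (size_t)c * R;
    for (int n = 0; n < N; ++n) {
      double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* md = mcol + (size_t)H * W * n;
      std::copy(md, md + (size_t)H * W, xc);
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// 2x transposed-convolution scatter: m is (H*W*N) x (4*Co) with columns
// ordered (dh, dw, co), dh fastest; output is [2H, 2W, Co, N].
// [[Rcpp::export]]
NumericVector up2_scatter(NumericMatrix m, int H, int W, int Co, int N) {
  int H2 = 2 * H, W2 = 2 * W;
  int R = H * W * N;
  NumericVector y((size_t)H2 * W2 * Co * N);
  double* yp = y.begin();
  const double* mp = m.begin();
  for (int co = 0; co < Co; ++co) {
    for (int dw = 0; dw < 2; ++dw) {
      for (int dh = 0; dh < 2; ++dh) {
        const double* mcol = mp + (size_t)(dh + 2 * dw + 4 * co) * R;
        for (int n = 0; n < N; ++n) {
          double* yc = yp + (size_t)H2 * W2 * (co + (size_t)Co * n);
          const double* md = mcol + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            double* ycw = yc + (size_t)H2 * (2 * w + dw) + dh;
            const double* mw = md + (size_t)H * w;
            for (int h = 0; h < H; ++h) ycw[2 * h] = mw[h];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H2, W2, Co, N);
  return y;
}

// adjoint of up2_scatter
// [[Rcpp::export]]
NumericMatrix up2_gather(NumericVector y, int H, int W, int Co, int N) {
  int H2 = 2 * H, W2 = 2 * W;
  int R = H * W * N;
  NumericMatrix m(R, 4 * Co);
  const double* yp = y.begin();
  double* mp = m.begin();
  for (int co = 0; co < Co; ++co) {
    for (int dw = 0; dw < 2; ++dw) {
      for (int dh = 0; dh < 2; ++dh) {
        double* mcol = mp + (size_t)(dh + 2 * dw + 4 * co) * R;
        for (int n = 0; n < N; ++n) {
          const double* yc = yp + (size_t)H2 * W2 * (co + (size_t)Co * n);
          double* md = mcol + (size_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const double* ycw = yc + (size_t)H2 * (2 * w + dw) + dh;
            double* mw = md + (size_t)H * w;
            for (int h = 0; h < H; ++h) mw[h] = ycw[2 * h];
          }
        }
      }
    }
  }
  return m;
}

// per-pixel channel statistics: out [H,W,2,N] with slice 1 = mean over C,
// slice 2 = max over C; amax records 0-based argmax channel per pixel.
// [[Rcpp::export]]
List pix_stats_fwd(NumericVector x, int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector out(HW * 2 * N);
  IntegerVector amax(HW * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + HW * C * n;
    double* omean = out.begin() + HW * 2 * n;
    double* omax = omean + HW;
    int* am = amax.begin() + HW * n;
    for (size_t i = 0; i < HW; ++i) {
      double s = xn[i], mx = xn[i];
      int ai = 0;
      for (int c = 1; c < C; ++c) {
        double v = xn[i + HW * c];
        s += v;
        if (v > mx) { mx = v; ai = c; }
      }
      omean[i] = s / C;
      omax[i] = mx;
      am[i] = ai;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, 2, N);
  return List::create(_["value"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector pix_stats_bwd(NumericVector d, IntegerVector amax,
                            int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * N);
  double* dxp = dx.begin();
  const double* dp = d.begin();
  for (int n = 0; n < N; ++n) {
    double* dn = dxp + HW * C * n;
    const double* dmean = dp + HW * 2 * n;
    const double* dmax = dmean + HW;
    const int* am = amax.begin() + HW * n;
    for (size_t i = 0; i < HW; ++i) {
      double g = dmean[i] / C;
      for (int c = 0; c < C; ++c) dn[i + HW * c] += g;
      dn[i + HW * am[i]] += dmax[i];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// multiply feature map by per-pixel gate s [H,W,1,N]
// [[Rcpp::export]]
NumericVector scale_spatial_fwd(NumericVector x, NumericVector s,
                                int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector y(HW * C * N);
  const double* xp = x.begin();
  const double* sp = s.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* sn = sp + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      double* yc = yp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = xc[i] * sn[i];
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// returns list(dx, ds) for y = x * s (s broadcast over channels)
// [[Rcpp::export]]
List scale_spatial_bwd(NumericVector d, NumericVector x, NumericVector s,
                       int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * N), ds(HW * N);
  const double* dp = d.begin();
  const double* xp = x.begin();
  const double* sp = s.begin();
  for (int n = 0; n < N; ++n) {
    const double* sn = sp + HW * n;
    double* dsn = ds.begin() + HW * n;
    for (int c = 0; c < C; ++c) {
      size_t off = HW * (c + (size_t)C * n);
      const double* dc = dp + off;
      const double* xc = xp + off;
      double* dxc = dx.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        dxc[i] = dc[i] * sn[i];
        dsn[i] += dc[i] * xc[i];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  ds.attr("dim") = IntegerVector::create(H, W, 1, N);
  return List::create(_["dx"] = dx, _["ds"] = ds);
}

// multiply feature map by per-channel gate g (C x N matrix)
// [[Rcpp::export]]
NumericVector scale_channels_fwd(NumericVector x, NumericMatrix g,
                                 int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector y(HW * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double gv = g(c, n);
      size_t off = HW * (c + (size_t)C * n);
      const double* xc = xp + off;
      double* yc = yp + off;
      for (size_t i = 0; i < HW; ++i) yc[i] = xc[i] * gv;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// returns list(dx, dg) for y = x * g
// [[Rcpp::export]]
List scale_channels_bwd(NumericVector d, NumericVector x, NumericMatrix g,
                        int H, int W, int C, int N) {
  size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * N);
  NumericMatrix dg(C, N);
  const double* dp = d.begin();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double gv = g(c, n), acc = 0.0;
      size_t off = HW * (c + (size_t)C * n);
      const double* dc = dp + off;
      const double* xc = xp + off;
      double* dxc = dx.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        dxc[i] = dc[i] * gv;
        acc += dc[i] * xc[i];
      }
      dg(c, n) = acc;
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dg"] = dg);
}
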