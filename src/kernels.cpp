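#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Tensor layout throughout: column-major arrays with dim (C, H, W, N),
// i.e. channel fastest. Conv weights: (Cin/groups, kh, kw, Cout).

static inline int out_dim(int in, int pad0, int pad1, int k, int dil, int stride) {
  return (in + pad0 + pad1 - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xd,
                        NumericVector w, IntegerVector wd,
                        NumericVector bias, bool has_bias,
                        int sh, int sw, int pt, int pb, int pl, int pr,
                        int dh, int dw, int groups) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cpg = wd[0], kh = wd[1], kw = wd[2], Cout = wd[3];
  const int Ho = out_dim(H, pt, pb, kh, dh, sh);
  const int Wo = out_dim(W, pl, pr, kw, dw, sw);
  const int Copg = Cout / groups;
  NumericVector y(Cout * (R_xlen_t)Ho * Wo * N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double *yo = py + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int co = 0; co < Cout; ++co) {
          const int g = co / Copg;
          double acc = has_bias ? bias[co] : 0.0;
          const double *wc = pw + (R_xlen_t)Cpg * kh * kw * co;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pl + j * dw;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - pt + i * dh;
              if (hi < 0 || hi >= H) continue;
              const double *xi = px + (R_xlen_t)g * Cpg +
                (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              const double *wk = wc + (R_xlen_t)Cpg * (i + kh * j);
              double s = 0.0;
              for (int c = 0; c < Cpg; ++c) s += xi[c] * wk[c];
              acc += s;
            }
          }
          yo[co] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw_input")]]
NumericVector conv2d_bw_input(NumericVector dy, IntegerVector yd,
                              NumericVector w, IntegerVector wd,
                              IntegerVector xd,
                              int sh, int sw, int pt, int pl,
                              int dh, int dw, int groups) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cpg = wd[0], kh = wd[1], kw = wd[2], Cout = wd[3];
  const int Ho = yd[1], Wo = yd[2];
  const int Copg = Cout / groups;
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *gyo = pdy + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int co = 0; co < Cout; ++co) {
          const double g_out = gyo[co];
          if (g_out == 0.0) continue;
          const int g = co / Copg;
          const double *wc = pw + (R_xlen_t)Cpg * kh * kw * co;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pl + j * dw;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - pt + i * dh;
              if (hi < 0 || hi >= H) continue;
              double *xi = pdx + (R_xlen_t)g * Cpg +
                (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              const double *wk = wc + (R_xlen_t)Cpg * (i + kh * j);
              for (int c = 0; c < Cpg; ++c) xi[c] += g_out * wk[c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}

// [[Rcpp::export(name = ".conv2d_bw_weight")]]
NumericVector conv2d_bw_weight(NumericVector dy, IntegerVector yd,
                               NumericVector x, IntegerVector xd,
                               IntegerVector wd,
                               int sh, int sw, int pt, int pl,
                               int dh, int dw, int groups) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cpg = wd[0], kh = wd[1], kw = wd[2], Cout = wd[3];
  const int Ho = yd[1], Wo = yd[2];
  const int Copg = Cout / groups;
  NumericVector dwt((R_xlen_t)Cpg * kh * kw * Cout);
  const double *pdy = dy.begin(), *px = x.begin();
  double *pdw = dwt.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *gyo = pdy + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int co = 0; co < Cout; ++co) {
          const double g_out = gyo[co];
          if (g_out == 0.0) continue;
          const int g = co / Copg;
          double *wc = pdw + (R_xlen_t)Cpg * kh * kw * co;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pl + j * dw;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - pt + i * dh;
              if (hi < 0 || hi >= H) continue;
              const double *xi = px + (R_xlen_t)g * Cpg +
                (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              double *wk = wc + (R_xlen_t)Cpg * (i + kh * j);
              for (int c = 0; c < Cpg; ++c) wk[c] += g_out * xi[c];
            }
          }
        }
      }
    }
  }
  dwt.attr("dim") = wd;
  return dwt;
}

// Bilinear resize, align_corners = FALSE (half-pixel centers, edges clamped).
// [[Rcpp::export(name = ".bilinear_fw")]]
NumericVector bilinear_fw(NumericVector x, IntegerVector xd, int Ho, int Wo) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      double ws = (wo + 0.5) * sw - 0.5;
      if (ws < 0) ws = 0; if (ws > W - 1) ws = W - 1;
      const int w0 = (int)ws, w1 = (w0 + 1 < W) ? w0 + 1 : w0;
      const double fw = ws - w0;
      for (int ho = 0; ho < Ho; ++ho) {
        double hs = (ho + 0.5) * sh - 0.5;
        if (hs < 0) hs = 0; if (hs > H - 1) hs = H - 1;
        const int h0 = (int)hs, h1 = (h0 + 1 < H) ? h0 + 1 : h0;
        const double fh = hs - h0;
        const double *a = px + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        const double *b = px + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        const double *c2 = px + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        const double *d = px + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        double *o = py + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        const double wa = (1 - fh) * (1 - fw), wb = fh * (1 - fw),
                     wc = (1 - fh) * fw, wdd = fh * fw;
        for (int c = 0; c < C; ++c)
          o[c] = wa * a[c] + wb * b[c] + wc * c2[c] + wdd * d[c];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".bilinear_bw")]]
NumericVector bilinear_bw(NumericVector dy, IntegerVector yd, IntegerVector xd) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Ho = yd[1], Wo = yd[2];
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      double ws = (wo + 0.5) * sw - 0.5;
      if (ws < 0) ws = 0; if (ws > W - 1) ws = W - 1;
      const int w0 = (int)ws, w1 = (w0 + 1 < W) ? w0 + 1 : w0;
      const double fw = ws - w0;
      for (int ho = 0; ho < Ho; ++ho) {
        double hs = (ho + 0.5) * sh - 0.5;
        if (hs < 0) hs = 0; if (hs > H - 1) hs = H - 1;
        const int h0 = (int)hs, h1 = (h0 + 1 < H) ? h0 + 1 : h0;
        const double fh = hs - h0;
        double *a = pdx + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        double *b = pdx + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        double *c2 = pdx + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        double *d = pdx + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        const double *o = pdy + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        const double wa = (1 - fh) * (1 - fw), wb = fh * (1 - fw),
                     wc = (1 - fh) * fw, wdd = fh * fw;
        for (int c = 0; c < C; ++c) {
          a[c] += wa * o[c]; b[c] += wb * o[c];
          c2[c] += wc * o[c]; d[c] += wdd * o[c];
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}

// Exact Euclidean distance transform of a binary mask (distance of every
// pixel to the nearest TRUE pixel) with the 1-based linear index of that
// nearest pixel. mask: H x W column-major logical-as-int.
// [[Rcpp::export(name = ".edt_nearest")]]
List edt_nearest(IntegerVector mask, int H, int W) {
  NumericVector dist((R_xlen_t)H * W);
  IntegerVector idx((R_xlen_t)H * W);
  // pass 1: per column, nearest seed row (O(H^2) per column)
  std::vector<double> d1((size_t)H * W, DBL_MAX);
  std::vector<int> r1((size_t)H * W, -1);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double best = DBL_MAX; int bi = -1;
      for (int rr = 0; rr < H; ++rr) {
        if (mask[rr + (R_xlen_t)H * c]) {
          double dd = (double)(r - rr) * (r - rr);
          if (dd < best) { best = dd; bi = rr; }
          if (rr > r && bi >= 0) break;  // rows sorted: once past r with a hit, distance only grows
        }
      }
      d1[(size_t)r + (size_t)H * c] = best;
      r1[(size_t)r + (size_t)H * c] = bi;
    }
  }
  // pass 2: per row, combine across columns
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double best = DBL_MAX; int bc = -1;
      for (int cc = 0; cc < W; ++cc) {
        double f = d1[(size_t)r + (size_t)H * cc];
        if (f == DBL_MAX) continue;
        double dd = f + (double)(c - cc) * (c - cc);
        if (dd < best) { best = dd; bc = cc; }
      }
      R_xlen_t k = r + (R_xlen_t)H * c;
      if (bc < 0) { dist[k] = R_PosInf; idx[k] = NA_INTEGER; }
      else {
        dist[k] = std::sqrt(best);
        idx[k] = r1[(size_t)r + (size_t)H * bc] + H * bc + 1;  // 1-based linear
      }
    }
  }
  dist.attr("dim") = IntegerVector::create(H, W);
  idx.attr("dim") = IntegerVector::create(H, W);
  return List::create(_["dist"] = dist, _["index"] = idx);
}
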