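#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are numeric arrays dim c(H, W, C), column-major, h fastest.
// im2col row index = kh + k*kw + k*k*c (matches R's flattening of a
// c(k, k, Cin, Cout) weight array); column index = ho + Ho*wo.

static inline int conv_out(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  const int Ho = conv_out(H, k, stride, pad, dil);
  const int Wo = conv_out(W, k, stride, pad, dil);
  NumericMatrix cols(k * k * C, Ho * Wo);
  const double* px = x.begin();
  double* pc = cols.begin();
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colidx = ho + Ho * wo;
      double* colp = pc + (size_t)colidx * rows;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh * dil;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + (size_t)H * w];
            colp[kh + k * kw + k * k * c] = v;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into an H x W x C array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  const int Ho = conv_out(H, k, stride, pad, dil);
  const int Wo = conv_out(W, k, stride, pad, dil);
  NumericVector x((size_t)H * W * C);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colidx = ho + Ho * wo;
      const double* colp = pc + (size_t)colidx * rows;
      for (int c = 0; c < C; ++c) {
        double* xc = px + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = wo * stride - pad + kw * dil;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = ho * stride - pad + kh * dil;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += colp[kh + k * kw + k * k * c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Depthwise convolution, weight dim c(k, k, C).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C,
                             NumericVector w, int k, int stride, int pad, int dil) {
  const int Ho = conv_out(H, k, stride, pad, dil);
  const int Wo = conv_out(W, k, stride, pad, dil);
  NumericVector y((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    const double* wc = w.begin() + (size_t)c * k * k;
    double* yc = y.begin() + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            acc += xc[hi + (size_t)H * wi] * wc[kh + k * kw];
          }
        }
        yc[ho + (size_t)Ho * wo] = acc;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_input_cpp(NumericVector dy, int H, int W, int C,
                                   NumericVector w, int k, int stride, int pad, int dil) {
  const int Ho = conv_out(H, k, stride, pad, dil);
  const int Wo = conv_out(W, k, stride, pad, dil);
  NumericVector dx((size_t)H * W * C);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + (size_t)c * H * W;
    const double* wc = w.begin() + (size_t)c * k * k;
    const double* dyc = dy.begin() + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (size_t)Ho * wo];
        if (g == 0.0) continue;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += g * wc[kh + k * kw];
          }
        }
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_weight_cpp(NumericVector dy, NumericVector x,
                                    int H, int W, int C,
                                    int k, int stride, int pad, int dil) {
  const int Ho = conv_out(H, k, stride, pad, dil);
  const int Wo = conv_out(W, k, stride, pad, dil);
  NumericVector dw((size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* dwc = dw.begin() + (size_t)c * k * k;
    const double* dyc = dy.begin() + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (size_t)Ho * wo];
        if (g == 0.0) continue;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            dwc[kh + k * kw] += g * xc[hi + (size_t)H * wi];
          }
        }
      }
  }
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return dw;
}

// Max pooling; returns pooled map plus 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int k, int stride) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf; int bidx = -1;
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride + kh, wi = wo * stride + kw;
            const double v = xc[hi + (size_t)H * wi];
            if (v > best) { best = v; bidx = hi + H * wi + H * W * c; }
          }
        const size_t o = ho + (size_t)Ho * wo + (size_t)Ho * Wo * c;
        y[o] = best;
        idx[o] = bidx + 1;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx, int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Connected-component labeling of a binary mask (H x W integer matrix,
// nonzero = foreground). Labels 1..k in scanline (row-by-row) discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dh8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dw8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dh4[4] = {-1, 0, 0, 1};
  const int dw4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dh = (connectivity == 8) ? dh8 : dh4;
  const int* dw = (connectivity == 8) ? dw8 : dw4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < nn; ++d) {
          const int nh = p.first + dh[d], nw = p.second + dw[d];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            q.push(std::make_pair(nh, nw));
          }
        }
      }
    }
  return lab;
}
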