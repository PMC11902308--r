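#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays dim c(H, W, C), column-major.
// im2col for a KxK kernel, stride 1, zero 'same' padding:
// returns (H*W) x (K*K*C); row p = flattened receptive field centred at pixel p.

// [[Rcpp::export]]
NumericMatrix im2col_same(NumericVector x, int H, int W, int C, int K) {
  int P = (K - 1) / 2;
  NumericMatrix out(H * W, K * K * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int col = kh + K * (kw + K * c);
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - P;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - P;
            if (ih < 0 || ih >= H) continue;
            out(h + H * w, col) = x[ih + H * (iw + W * c)];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_same: scatter-add column gradients back to the input array.
// [[Rcpp::export]]
NumericVector col2im_same(NumericMatrix cols, int H, int W, int C, int K) {
  int P = (K - 1) / 2;
  NumericVector dx(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int col = kh + K * (kw + K * c);
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - P;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - P;
            if (ih < 0 || ih >= H) continue;
            dx[ih + H * (iw + W * c)] += cols(h + H * w, col);
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling, stride 2 (H, W assumed even). Returns pooled values and the
// 1-based linear argmax index into the input array, for the backward scatter.
// [[Rcpp::export]]
List maxpool2x2(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = R_NegInf; int besti = -1;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            int i = (2 * h + dh) + H * ((2 * w + dw) + W * c);
            if (x[i] > best) { best = x[i]; besti = i; }
          }
        }
        int o = h + Ho * (w + Wo * c);
        out[o] = best;
        idx[o] = besti + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}
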