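// Memory-movement primitives for the CPU conv-net engine.
//
// Batches live in "flat" layout: a numeric matrix with N*H*W rows and C
// columns. Row r (0-based) maps to image n = r / (H*W) and within-image
// column-major spatial offset o = r % (H*W), i.e. i = o % H, j = o / H.
// All matrix products are done in R via BLAS; C++ only shuffles memory.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Patch matrix for a 3x3 "same" convolution (stride 1, zero padding).
// Output has N*H*W rows and 9*C columns; column block for offset
// o = (dj+1)*3 + (di+1) and channel c is o*C + c. When `ones` is true
// a trailing all-ones column is appended so the conv bias can ride
// along in the same matrix product.
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& X, int H, int W, int N,
                      bool ones = false) {
  const int C = X.ncol();
  const int HW = H * W;
  NumericMatrix out(N * HW, 9 * C + (ones ? 1 : 0));
  if (ones) {
    double* lastc = &out(0, 9 * C);
    std::fill(lastc, lastc + (size_t)N * HW, 1.0);
  }
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int o = 0; o < 9; ++o) {
      const int di = o % 3 - 1;
      const int dj = o / 3 - 1;
      double* oc = &out(0, o * C + c);
      for (int n = 0; n < N; ++n) {
        const double* xim = xc + (size_t)n * HW;
        double* oim = oc + (size_t)n * HW;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;  // zero padding
          const double* xcol = xim + sj * H;
          double* ocol = oim + j * H;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) ocol[i] = xcol[i + di];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-adds a gradient w.r.t. the patch matrix
// back onto the input layout.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dXcol, int H, int W, int N, int C) {
  const int HW = H * W;
  NumericMatrix out(N * HW, C);
  for (int c = 0; c < C; ++c) {
    double* xc = &out(0, c);
    for (int o = 0; o < 9; ++o) {
      const int di = o % 3 - 1;
      const int dj = o / 3 - 1;
      const double* oc = &dXcol(0, o * C + c);
      for (int n = 0; n < N; ++n) {
        double* xim = xc + (size_t)n * HW;
        const double* oim = oc + (size_t)n * HW;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xim + sj * H;
          const double* ocol = oim + j * H;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) xcol[i + di] += ocol[i];
        }
      }
    }
  }
  return out;
}

// 2x2 average pooling, stride 2. H and W must be even.
// [[Rcpp::export]]
NumericMatrix avgpool2_fw(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  NumericMatrix out(N * HWo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* xim = xc + (size_t)n * HW;
      double* oim = oc + (size_t)n * HWo;
      for (int j = 0; j < Wo; ++j) {
        const double* c0 = xim + (2 * j) * H;
        const double* c1 = xim + (2 * j + 1) * H;
        double* ocol = oim + j * Ho;
        for (int i = 0; i < Ho; ++i)
          ocol[i] = 0.25 * (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]);
      }
    }
  }
  return out;
}

// Backward of 2x2 average pooling: spreads each output gradient evenly
// over its 2x2 input window.
// [[Rcpp::export]]
NumericMatrix avgpool2_bw(const NumericMatrix& dY, int H, int W, int N) {
  const int C = dY.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  NumericMatrix out(N * HW, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dY(0, c);
    double* oc = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* gim = gc + (size_t)n * HWo;
      double* oim = oc + (size_t)n * HW;
      for (int j = 0; j < Wo; ++j) {
        double* c0 = oim + (2 * j) * H;
        double* c1 = oim + (2 * j + 1) * H;
        const double* gcol = gim + j * Ho;
        for (int i = 0; i < Ho; ++i) {
          const double g = 0.25 * gcol[i];
          c0[2 * i] = g; c0[2 * i + 1] = g; c1[2 * i] = g; c1[2 * i + 1] = g;
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2, recording flat argmax positions (1-based
// row indices into the input) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fw(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  NumericMatrix out(N * HWo, C);
  IntegerMatrix amax(N * HWo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    int* ac = &amax(0, c);
    for (int n = 0; n < N; ++n) {
      const size_t xoff = (size_t)n * HW;
      const size_t ooff = (size_t)n * HWo;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int base = (2 * j) * H + 2 * i;
          const int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          double bv = xc[xoff + best];
          for (int t = 1; t < 4; ++t)
            if (xc[xoff + cand[t]] > bv) { best = cand[t]; bv = xc[xoff + best]; }
          oc[ooff + j * Ho + i] = bv;
          ac[ooff + j * Ho + i] = (int)(xoff + best) + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// Backward of 2x2 max pooling: routes each gradient to its argmax.
// [[Rcpp::export]]
NumericMatrix maxpool2_bw(const NumericMatrix& dY, const IntegerMatrix& amax,
                          int H, int W, int N) {
  const int C = dY.ncol();
  NumericMatrix out(N * H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dY(0, c);
    const int* ac = &amax(0, c);
    double* oc = &out(0, c);
    const int nr = dY.nrow();
    for (int r = 0; r < nr; ++r) oc[ac[r] - 1] += gc[r];
  }
  return out;
}

// Crop/flip gather for a batch: ri and cj are s x n matrices of
// 1-based source row/column indices per instance; images are
// s x s x channels arrays. Output is the flat stacked batch.
// [[Rcpp::export]]
NumericMatrix gather_stack(List images, IntegerVector idx,
                           const IntegerMatrix& ri,
                           const IntegerMatrix& cj, int channels) {
  const int s = ri.nrow();
  const int n = idx.size();
  const int hw = s * s;
  NumericMatrix out(n * hw, channels);
  for (int t = 0; t < n; ++t) {
    NumericVector img = images[idx[t] - 1];
    const double* ip = REAL(img);
    for (int c = 0; c < channels; ++c) {
      double* op = &out((size_t)t * hw, c);
      const double* icp = ip + (size_t)c * hw;
      for (int j = 0; j < s; ++j) {
        const double* scol = icp + (size_t)(cj(j, t) - 1) * s;
        double* ocol = op + (size_t)j * s;
        for (int i = 0; i < s; ++i) ocol[i] = scol[ri(i, t) - 1];
      }
    }
  }
  return out;
}
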