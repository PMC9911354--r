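#include <Rcpp.h>
using namespace Rcpp;

// Direct 3x3(x3) same-padding convolution kernels.
//
// Activations are N x C matrices, N = prod(sp) voxels in R array order
// (first spatial dimension fastest).  Weights are (K*C_in) x C_out with
// K = 3^nd; row c*K + k holds the weight for input channel c and kernel
// offset k (offsets enumerated first-dimension fastest, each in
// {-1, 0, 1}).  Out-of-bounds input samples are treated as zero.
//
// The three passes (forward, gradient w.r.t. input, gradient w.r.t.
// weights) share the same loop structure; each (c, f, k) pass streams two
// N-length columns, which keeps everything in cache.

// [[Rcpp::export]]
NumericMatrix conv3_fw(NumericMatrix x, IntegerVector sp, NumericMatrix W,
                       NumericVector b) {
  const int n1 = sp[0], n2 = sp[1], n3 = sp[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const int C = x.ncol();
  const int F = W.ncol();
  const int K = 27;
  NumericMatrix out(N, F);
  double* op = REAL(out);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  const R_xlen_t wld = W.nrow();
  for (int f = 0; f < F; ++f)
    std::fill(op + (R_xlen_t)f * N, op + (R_xlen_t)(f + 1) * N, b[f]);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      double* of = op + (R_xlen_t)f * N;
      int k = 0;
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1, ++k) {
            const double w = wp[(R_xlen_t)f * wld + (R_xlen_t)c * K + k];
            if (w == 0.0) continue;
            const int lo3 = std::max(0, -d3), hi3 = n3 - std::max(0, d3);
            const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
            const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
            for (int i3 = lo3; i3 < hi3; ++i3)
              for (int i2 = lo2; i2 < hi2; ++i2) {
                const double* src =
                  xc + (((R_xlen_t)(i3 + d3) * n2 + (i2 + d2)) * n1 + d1);
                double* dst = of + ((R_xlen_t)i3 * n2 + i2) * n1;
                for (int i1 = lo1; i1 < hi1; ++i1)
                  dst[i1] += w * src[i1];
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix conv3_bw_x(NumericMatrix dy, IntegerVector sp,
                         NumericMatrix W, int C) {
  const int n1 = sp[0], n2 = sp[1], n3 = sp[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const int F = W.ncol();
  const int K = 27;
  NumericMatrix dx(N, C);
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  const double* wp = REAL(W);
  const R_xlen_t wld = W.nrow();
  for (int c = 0; c < C; ++c) {
    double* dc = dp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      const double* gf = gp + (R_xlen_t)f * N;
      int k = 0;
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1, ++k) {
            const double w = wp[(R_xlen_t)f * wld + (R_xlen_t)c * K + k];
            if (w == 0.0) continue;
            // dx[v + d] += w * dy[v]: iterate over valid v
            const int lo3 = std::max(0, -d3), hi3 = n3 - std::max(0, d3);
            const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
            const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
            for (int i3 = lo3; i3 < hi3; ++i3)
              for (int i2 = lo2; i2 < hi2; ++i2) {
                double* dst =
                  dc + (((R_xlen_t)(i3 + d3) * n2 + (i2 + d2)) * n1 + d1);
                const double* src = gf + ((R_xlen_t)i3 * n2 + i2) * n1;
                for (int i1 = lo1; i1 < hi1; ++i1)
                  dst[i1] += w * src[i1];
              }
          }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix conv3_bw_w(NumericMatrix x, NumericMatrix dy,
                         IntegerVector sp) {
  const int n1 = sp[0], n2 = sp[1], n3 = sp[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const int C = x.ncol();
  const int F = dy.ncol();
  const int K = 27;
  NumericMatrix dW((R_xlen_t)K * C, F);
  double* wp = REAL(dW);
  const double* xp = REAL(x);
  const double* gp = REAL(dy);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      const double* gf = gp + (R_xlen_t)f * N;
      int k = 0;
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1, ++k) {
            const int lo3 = std::max(0, -d3), hi3 = n3 - std::max(0, d3);
            const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
            const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
            double acc = 0.0;
            for (int i3 = lo3; i3 < hi3; ++i3)
              for (int i2 = lo2; i2 < hi2; ++i2) {
                const double* src =
                  xc + (((R_xlen_t)(i3 + d3) * n2 + (i2 + d2)) * n1 + d1);
                const double* g = gf + ((R_xlen_t)i3 * n2 + i2) * n1;
                for (int i1 = lo1; i1 < hi1; ++i1)
                  acc += g[i1] * src[i1];
              }
            wp[(R_xlen_t)f * K * C + (R_xlen_t)c * K + k] = acc;
          }
    }
  }
  return dW;
}

// ---- 2D variants -------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix conv2_fw(NumericMatrix x, IntegerVector sp, NumericMatrix W,
                       NumericVector b) {
  const int n1 = sp[0], n2 = sp[1];
  const R_xlen_t N = (R_xlen_t)n1 * n2;
  const int C = x.ncol();
  const int F = W.ncol();
  const int K = 9;
  NumericMatrix out(N, F);
  double* op = REAL(out);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  const R_xlen_t wld = W.nrow();
  for (int f = 0; f < F; ++f)
    std::fill(op + (R_xlen_t)f * N, op + (R_xlen_t)(f + 1) * N, b[f]);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      double* of = op + (R_xlen_t)f * N;
      int k = 0;
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1, ++k) {
          const double w = wp[(R_xlen_t)f * wld + (R_xlen_t)c * K + k];
          if (w == 0.0) continue;
          const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
          const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
          for (int i2 = lo2; i2 < hi2; ++i2) {
            const double* src = xc + ((R_xlen_t)(i2 + d2) * n1 + d1);
            double* dst = of + (R_xlen_t)i2 * n1;
            for (int i1 = lo1; i1 < hi1; ++i1) dst[i1] += w * src[i1];
          }
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix conv2_bw_x(NumericMatrix dy, IntegerVector sp,
                         NumericMatrix W, int C) {
  const int n1 = sp[0], n2 = sp[1];
  const R_xlen_t N = (R_xlen_t)n1 * n2;
  const int F = W.ncol();
  const int K = 9;
  NumericMatrix dx(N, C);
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  const double* wp = REAL(W);
  const R_xlen_t wld = W.nrow();
  for (int c = 0; c < C; ++c) {
    double* dc = dp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      const double* gf = gp + (R_xlen_t)f * N;
      int k = 0;
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1, ++k) {
          const double w = wp[(R_xlen_t)f * wld + (R_xlen_t)c * K + k];
          if (w == 0.0) continue;
          const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
          const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
          for (int i2 = lo2; i2 < hi2; ++i2) {
            double* dst = dc + ((R_xlen_t)(i2 + d2) * n1 + d1);
            const double* src = gf + (R_xlen_t)i2 * n1;
            for (int i1 = lo1; i1 < hi1; ++i1) dst[i1] += w * src[i1];
          }
        }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix conv2_bw_w(NumericMatrix x, NumericMatrix dy,
                         IntegerVector sp) {
  const int n1 = sp[0], n2 = sp[1];
  const R_xlen_t N = (R_xlen_t)n1 * n2;
  const int C = x.ncol();
  const int F = dy.ncol();
  const int K = 9;
  NumericMatrix dW((R_xlen_t)K * C, F);
  double* wp = REAL(dW);
  const double* xp = REAL(x);
  const double* gp = REAL(dy);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * N;
    for (int f = 0; f < F; ++f) {
      const double* gf = gp + (R_xlen_t)f * N;
      int k = 0;
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1, ++k) {
          const int lo2 = std::max(0, -d2), hi2 = n2 - std::max(0, d2);
          const int lo1 = std::max(0, -d1), hi1 = n1 - std::max(0, d1);
          double acc = 0.0;
          for (int i2 = lo2; i2 < hi2; ++i2) {
            const double* src = xc + ((R_xlen_t)(i2 + d2) * n1 + d1);
            const double* g = gf + (R_xlen_t)i2 * n1;
            for (int i1 = lo1; i1 < hi1; ++i1) acc += g[i1] * src[i1];
          }
          wp[(R_xlen_t)f * K * C + (R_xlen_t)c * K + k] = acc;
        }
    }
  }
  return dW;
}

// Connected-component labelling of a binary mask (flat 0/1 integer vector
// in R array order) under 6- or 26-connectivity, by flood fill.
// Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components(IntegerVector mask, IntegerVector sp,
                               int connectivity) {
  const int n1 = sp[0], n2 = sp[1], n3 = sp[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> offs;
  std::vector<int> od1, od2, od3;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        if (d1 == 0 && d2 == 0 && d3 == 0) continue;
        int manh = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (connectivity == 6 && manh != 1) continue;
        od1.push_back(d1); od2.push_back(d2); od3.push_back(d3);
        offs.push_back((R_xlen_t)d1 + (R_xlen_t)d2 * n1 +
                       (R_xlen_t)d3 * n1 * n2);
      }
  const int nOff = (int)offs.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t v = 0; v < N; ++v) {
    if (!mask[v] || lab[v]) continue;
    lab[v] = ++next;
    stack.push_back(v);
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      const int i1 = (int)(u % n1);
      const int i2 = (int)((u / n1) % n2);
      const int i3 = (int)(u / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < nOff; ++k) {
        const int j1 = i1 + od1[k], j2 = i2 + od2[k], j3 = i3 + od3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        const R_xlen_t w = u + offs[k];
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
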