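#include <Rcpp.h>
using namespace Rcpp;

// im2col/col2im kernels backing the in-package conv layers; the actual
// multiply runs through R's BLAS. Layouts (column-major):
//   activations x: dim (H, W, C)
//   patch matrix: (Ho*Wo) x (k*k*C), row index ho + Ho*wo,
//                 column index kh + k*kw + k*k*c  (matches matrix(w) with
//                 weights stored as dim (k, k, Cin, Cout))

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int colIdx = kh + k * kw + k * k * c;
        double* op = &out(0, colIdx);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          double* opw = op + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) continue;   // stays zero
          const double* xcol = xc + (size_t)H * wi;
          int hi0 = -pad + kh;               // hi = ho*stride + hi0
          int hoLo = 0, hoHi = Ho - 1;
          if (stride == 1) {
            if (hi0 < 0) hoLo = -hi0;
            if (hi0 + Ho - 1 >= H) hoHi = H - 1 - hi0;
            for (int ho = hoLo; ho <= hoHi; ++ho)
              opw[ho] = xcol[ho + hi0];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + hi0;
              if (hi >= 0 && hi < H) opw[ho] = xcol[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * C);
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int colIdx = kh + k * kw + k * k * c;
        const double* op = &cols(0, colIdx);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double* opw = op + (size_t)Ho * wo;
          double* xcol = xc + (size_t)H * wi;
          int hi0 = -pad + kh;
          if (stride == 1) {
            int hoLo = 0, hoHi = Ho - 1;
            if (hi0 < 0) hoLo = -hi0;
            if (hi0 + Ho - 1 >= H) hoHi = H - 1 - hi0;
            for (int ho = hoLo; ho <= hoHi; ++ho)
              xcol[ho + hi0] += opw[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + hi0;
              if (hi >= 0 && hi < H) xcol[hi] += opw[ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
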