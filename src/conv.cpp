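#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
using namespace Rcpp;

// Convolution via per-sample im2col into a small reusable buffer followed by
// BLAS dgemm, so the column matrix stays cache-resident instead of being
// materialized for the whole batch. `idx` holds 1-based linear indices into
// one sample's (spatial..., channel) block; 0 marks a zero-padded position.

// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(NumericVector x, IntegerVector idx,
                               NumericMatrix W, int voxels, int B,
                               int krows, int npos) {
  const int c_out = W.nrow();
  NumericMatrix y(c_out, (R_xlen_t)npos * B);
  std::vector<double> cols((size_t)krows * npos);
  const double* xo = REAL(x);
  const double* wp = REAL(W);
  double* yo = REAL(y);
  const int* ip = INTEGER(idx);
  const R_xlen_t L = (R_xlen_t)krows * npos;
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    const double* xb = xo + (R_xlen_t)b * voxels;
    for (R_xlen_t j = 0; j < L; ++j) {
      int k = ip[j];
      cols[j] = k ? xb[k - 1] : 0.0;
    }
    F77_CALL(dgemm)("N", "N", &c_out, &npos, &krows, &one, wp, &c_out,
                    cols.data(), &krows, &zero,
                    yo + (R_xlen_t)b * c_out * npos, &c_out FCONE FCONE);
  }
  return y;
}

// Backward pass: dW accumulated over samples, dx scattered through the same
// index plan. dY is (c_out x npos*B); x is the forward input.

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericVector dY, IntegerVector idx,
                       NumericMatrix W, int voxels, int B,
                       int krows, int npos, bool need_dx) {
  const int c_out = W.nrow();
  NumericMatrix dW(c_out, krows);
  NumericMatrix dx(need_dx ? voxels : 1, need_dx ? B : 1);
  std::vector<double> cols((size_t)krows * npos);
  std::vector<double> dcols((size_t)krows * npos);
  const double* xo = REAL(x);
  const double* dyo = REAL(dY);
  const double* wp = REAL(W);
  double* dwp = REAL(dW);
  double* dxo = REAL(dx);
  const int* ip = INTEGER(idx);
  const R_xlen_t L = (R_xlen_t)krows * npos;
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    const double* xb = xo + (R_xlen_t)b * voxels;
    const double* dyb = dyo + (R_xlen_t)b * c_out * npos;
    for (R_xlen_t j = 0; j < L; ++j) {
      int k = ip[j];
      cols[j] = k ? xb[k - 1] : 0.0;
    }
    // dW += dY_b %*% t(cols)
    F77_CALL(dgemm)("N", "T", &c_out, &krows, &npos, &one, dyb, &c_out,
                    cols.data(), &krows, &one, dwp, &c_out FCONE FCONE);
    if (need_dx) {
      // dcols = t(W) %*% dY_b
      F77_CALL(dgemm)("T", "N", &krows, &npos, &c_out, &one, wp, &c_out,
                      dyb, &c_out, &zero, dcols.data(), &krows FCONE FCONE);
      double* dxb = dxo + (R_xlen_t)b * voxels;
      for (R_xlen_t j = 0; j < L; ++j) {
        int k = ip[j];
        if (k) dxb[k - 1] += dcols[j];
      }
    }
  }
  return List::create(Named("dW") = dW, Named("dx") = dx);
}
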