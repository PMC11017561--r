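// Elementwise and data-movement kernels for the training loop. Everything
// here is numerically plain (no BLAS); matrix products stay in R where they
// hit the system BLAS. Functions suffixed _inplace mutate their first
// argument and must only be called on freshly allocated objects owned by
// the caller.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

// GELU(x) = x * Phi(x) with the exact Gaussian CDF.
// [[Rcpp::export]]
NumericVector cpp_gelu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    po[i] = px[i] * 0.5 * std::erfc(-px[i] * INV_SQRT2);
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// d GELU / dx = Phi(x) + x * phi(x), times the upstream gradient.
// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector dout, NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* px = REAL(x);
  const double* pd = REAL(dout);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = px[i];
    double phi = INV_SQRT2PI * std::exp(-0.5 * xi * xi);
    double Phi = 0.5 * std::erfc(-xi * INV_SQRT2);
    po[i] = pd[i] * (Phi + xi * phi);
  }
  out.attr("dim") = dout.attr("dim");
  return out;
}

// Swish(x) = x * sigmoid(x).
// [[Rcpp::export]]
NumericVector cpp_swish_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double s = 1.0 / (1.0 + std::exp(-px[i]));
    po[i] = px[i] * s;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_swish_bwd(NumericVector dout, NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* px = REAL(x);
  const double* pd = REAL(dout);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = px[i];
    double s = 1.0 / (1.0 + std::exp(-xi));
    po[i] = pd[i] * s * (1.0 + xi * (1.0 - s));
  }
  out.attr("dim") = dout.attr("dim");
  return out;
}

// Adds a bias vector to every row of a matrix, in place.
// [[Rcpp::export]]
void cpp_add_bias_inplace(NumericMatrix m, NumericVector b) {
  R_xlen_t nr = m.nrow(), nc = m.ncol();
  if (b.size() != nc) stop("bias length does not match columns");
  double* p = REAL(m);
  const double* pb = REAL(b);
  for (R_xlen_t j = 0; j < nc; ++j) {
    double bj = pb[j];
    double* col = p + j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) col[i] += bj;
  }
}

// One Adam update, in place on the parameter and both moment buffers.
// bc1/bc2 are the bias-correction factors 1 - beta^t.
// [[Rcpp::export]]
void cpp_adam_inplace(NumericVector p, NumericVector m, NumericVector v,
                      NumericVector g, double lr, double beta1, double beta2,
                      double bc1, double bc2, double eps) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n) {
    stop("adam buffers must have equal length");
  }
  double* pp = REAL(p);
  double* pm = REAL(m);
  double* pv = REAL(v);
  const double* pg = REAL(g);
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  const double step = lr / bc1, inv_sqrt_bc2 = 1.0 / std::sqrt(bc2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = beta1 * pm[i] + a1 * gi;
    double vi = beta2 * pv[i] + a2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= step * mi / (std::sqrt(vi) * inv_sqrt_bc2 + eps);
  }
}

// im2col for 1-D convolution with stride 1 and symmetric zero padding.
// x has dim (n, L, c); result is the (n*L) x (h*c) patch matrix whose
// column (t, ch) holds x[, l + t - 1 - pad, ch].
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int n, int L, int c, int h) {
  int pad = (h - 1) / 2;
  NumericMatrix out(n * L, h * c);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int ch = 0; ch < c; ++ch) {
    for (int t = 0; t < h; ++t) {
      int o = t - pad;
      R_xlen_t col = (R_xlen_t)(ch * h + t) * n * L;
      R_xlen_t src = (R_xlen_t)ch * n * L;
      for (int l = 0; l < L; ++l) {
        int ls = l + o;
        if (ls < 0 || ls >= L) continue;
        std::memcpy(po + col + (R_xlen_t)l * n,
                    px + src + (R_xlen_t)ls * n, n * sizeof(double));
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-adds the patch gradient back onto the
// (n, L, c) input gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dp, int n, int L, int c, int h) {
  int pad = (h - 1) / 2;
  NumericVector out(Dimension(n, L, c));
  const double* pd = REAL(dp);
  double* po = REAL(out);
  for (int ch = 0; ch < c; ++ch) {
    for (int t = 0; t < h; ++t) {
      int o = t - pad;
      R_xlen_t col = (R_xlen_t)(ch * h + t) * n * L;
      R_xlen_t dst = (R_xlen_t)ch * n * L;
      for (int l = 0; l < L; ++l) {
        int ls = l + o;
        if (ls < 0 || ls >= L) continue;
        const double* src = pd + col + (R_xlen_t)l * n;
        double* d = po + dst + (R_xlen_t)ls * n;
        for (int i = 0; i < n; ++i) d[i] += src[i];
      }
    }
  }
  return out;
}

// Transpose the last two axes of a (B, N, D) array -> (B, D, N).
// [[Rcpp::export]]
NumericVector cpp_permute_nd(NumericVector x, int B, int N, int D) {
  NumericVector out(Dimension(B, D, N));
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int d = 0; d < D; ++d) {
    for (int n = 0; n < N; ++n) {
      const double* src = px + ((R_xlen_t)d * N + n) * B;
      double* dst = po + ((R_xlen_t)n * D + d) * B;
      std::memcpy(dst, src, B * sizeof(double));
    }
  }
  return out;
}
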