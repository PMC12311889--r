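// Hot numeric kernels for the 1-D convolutional codec.
//
// Activation arrays are [n, L, C] (batch fastest), so a (length, channel)
// slab is n contiguous doubles: im2col/col2im reduce to memcpy / axpy over
// such slabs, and the batchnorm helpers avoid the large rep() temporaries
// a pure-R implementation needs.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline void copyDim(const NumericVector& from, NumericVector& to) {
  if (from.hasAttribute("dim")) to.attr("dim") = from.attr("dim");
}


// Patch matrix [n*M, C*k]; column block j holds the C channels of kernel
// tap j, which reads input position t*stride + j - padL (0-based).
// [[Rcpp::export]]
NumericMatrix cppIm2col(const NumericVector& X, int n, int L, int C,
                        int k, int stride, int padL) {
  const int M = L / stride;
  NumericMatrix out = no_init((R_xlen_t)n * M, (R_xlen_t)C * k);
  const double* x = X.begin();
  double* o = out.begin();
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      double* col = o + ((R_xlen_t)j * C + c) * n * M;
      for (int t = 0; t < M; ++t) {
        const int l = t * stride + j - padL;
        if (l < 0 || l >= L) {  // zero padding
          std::memset(col + (R_xlen_t)t * n, 0, n * sizeof(double));
          continue;
        }
        std::memcpy(col + (R_xlen_t)t * n,
                    x + ((R_xlen_t)c * L + l) * n,
                    n * sizeof(double));
      }
    }
  }
  return out;
}

// Adjoint of cppIm2col: scatter-add patch values back onto [n, L, C].
// [[Rcpp::export]]
NumericVector cppCol2im(const NumericMatrix& Xcol, int n, int C, int L,
                        int k, int stride, int padL) {
  const int M = Xcol.nrow() / n;
  NumericVector out((R_xlen_t)n * L * C);
  const double* xc = Xcol.begin();
  double* o = out.begin();
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      const double* col = xc + ((R_xlen_t)j * C + c) * n * M;
      for (int t = 0; t < M; ++t) {
        const int l = t * stride + j - padL;
        if (l < 0 || l >= L) continue;
        double* dst = o + ((R_xlen_t)c * L + l) * n;
        const double* src = col + (R_xlen_t)t * n;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  out.attr("dim") = Dimension(n, L, C);
  return out;
}

// Per-channel affine map Y[i,l,c] = X[i,l,c] * scale[c] + shift[c].
// [[Rcpp::export]]
NumericVector cppChannelAffine(const NumericVector& X, int m, int C,
                               const NumericVector& scale,
                               const NumericVector& shift) {
  NumericVector out(no_init((R_xlen_t)m * C));
  const double* x = X.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double a = scale[c], b = shift[c];
    const double* xc = x + (R_xlen_t)c * m;
    double* oc = o + (R_xlen_t)c * m;
    for (int i = 0; i < m; ++i) oc[i] = xc[i] * a + b;
  }
  return out;
}

// Fused batchnorm apply: Xhat = (X - mu) * inv, Y = Xhat * gamma + beta,
// both in one read pass.
// [[Rcpp::export]]
List cppBnApply(const NumericVector& X, int m, int C,
                const NumericVector& mu, const NumericVector& inv,
                const NumericVector& gamma, const NumericVector& beta) {
  NumericVector xhat(no_init((R_xlen_t)m * C));
  NumericVector y(no_init((R_xlen_t)m * C));
  const double* x = X.begin();
  double* h = xhat.begin();
  double* o = y.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = mu[c], ic = inv[c], gc = gamma[c], bc = beta[c];
    const R_xlen_t off = (R_xlen_t)c * m;
    for (int i = 0; i < m; ++i) {
      const double xh = (x[off + i] - mc) * ic;
      h[off + i] = xh;
      o[off + i] = xh * gc + bc;
    }
  }
  copyDim(X, xhat);
  copyDim(X, y);
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Fused batchnorm backward reductions: per channel
//   dgamma = sum(dY * Xhat), dbeta = sum(dY),
//   m1 = mean(dY) * gamma, m2 = mean(dY * Xhat) * gamma
// (m1/m2 are the means of dXhat and dXhat*Xhat without materializing dXhat).
// [[Rcpp::export]]
List cppBnBackwardStats(const NumericVector& dY, const NumericVector& Xhat,
                        int m, int C, const NumericVector& gamma) {
  NumericVector dgamma(C), dbeta(C), m1(C), m2(C);
  const double* dy = dY.begin();
  const double* h = Xhat.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t off = (R_xlen_t)c * m;
    double s = 0.0, sh = 0.0;
    for (int i = 0; i < m; ++i) {
      s += dy[off + i];
      sh += dy[off + i] * h[off + i];
    }
    dgamma[c] = sh;
    dbeta[c] = s;
    m1[c] = s / m * gamma[c];
    m2[c] = sh / m * gamma[c];
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["m1"] = m1, _["m2"] = m2);
}

// Fused batchnorm backward input gradient (training mode):
//   dX = (dY * gamma - m1 - Xhat * m2) * inv
// [[Rcpp::export]]
NumericVector cppBnBackwardInput(const NumericVector& dY,
                                 const NumericVector& Xhat, int m, int C,
                                 const NumericVector& gamma,
                                 const NumericVector& inv,
                                 const NumericVector& m1,
                                 const NumericVector& m2) {
  NumericVector out(no_init((R_xlen_t)m * C));
  const double* dy = dY.begin();
  const double* h = Xhat.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double gc = gamma[c], ic = inv[c], a1 = m1[c], a2 = m2[c];
    const R_xlen_t off = (R_xlen_t)c * m;
    for (int i = 0; i < m; ++i)
      o[off + i] = (dy[off + i] * gc - a1 - h[off + i] * a2) * ic;
  }
  copyDim(dY, out);
  return out;
}

// Per-channel bias add followed by ReLU, one pass.
// [[Rcpp::export]]
NumericVector cppBiasRelu(const NumericVector& X, int m, int C,
                          const NumericVector& bias) {
  NumericVector out(no_init((R_xlen_t)m * C));
  const double* x = X.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double b = bias[c];
    const R_xlen_t off = (R_xlen_t)c * m;
    for (int i = 0; i < m; ++i) {
      const double v = x[off + i] + b;
      o[off + i] = v > 0.0 ? v : 0.0;
    }
  }
  return out;
}

// ReLU forward (no bias), one pass.
// [[Rcpp::export]]
NumericVector cppRelu(const NumericVector& X) {
  NumericVector out(no_init(X.size()));
  const double* x = X.begin();
  double* o = out.begin();
  const R_xlen_t n = X.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = x[i] > 0.0 ? x[i] : 0.0;
  copyDim(X, out);
  return out;
}

// ReLU backward using the forward *output* (out > 0 iff input > 0).
// [[Rcpp::export]]
NumericVector cppReluGrad(const NumericVector& dY, const NumericVector& out) {
  NumericVector dx(no_init(dY.size()));
  const double* dy = dY.begin();
  const double* o = out.begin();
  double* d = dx.begin();
  const R_xlen_t n = dY.size();
  for (R_xlen_t i = 0; i < n; ++i) d[i] = o[i] > 0.0 ? dy[i] : 0.0;
  copyDim(dY, dx);
  return dx;
}

// One-pass per-channel mean and (population) variance over an [m, C] view.
// [[Rcpp::export]]
List cppChannelMeanVar(const NumericVector& X, int m, int C) {
  NumericVector mu(C), va(C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * m;
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += xc[i];
    const double mean = s / m;
    double q = 0.0;
    for (int i = 0; i < m; ++i) {
      const double d = xc[i] - mean;
      q += d * d;
    }
    mu[c] = mean;
    va[c] = q / m;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}
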