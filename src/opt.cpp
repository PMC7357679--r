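// In-place optimizer kernels.  The R callers guarantee exclusive ownership
// of the parameter and moment buffers (fresh copies are made when a trainer
// takes over a parameter set), so updating in place is safe and avoids
// re-allocating every tensor on every mini-batch.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adam with the bias correction folded into the step size `a`.
// [[Rcpp::export]]
void adam_step_(NumericVector p, NumericVector m, NumericVector v,
                NumericVector g, double a, double beta1, double beta2,
                double eps) {
  R_xlen_t n = p.size();
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pp[i] -= a * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}

// Momentum SGD.
// [[Rcpp::export]]
void sgd_step_(NumericVector p, NumericVector v, NumericVector g,
               double lr, double momentum) {
  R_xlen_t n = p.size();
  double *pp = REAL(p), *pv = REAL(v), *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    pv[i] = momentum * pv[i] + pg[i];
    pp[i] -= lr * pv[i];
  }
}

// Fused bias add + rectifier: z[i,j] = max(z[i,j] + b[j], 0); returns the
// activation mask needed for backpropagation.
// [[Rcpp::export]]
LogicalMatrix bias_relu_(NumericMatrix z, NumericVector b) {
  int nr = z.nrow(), nc = z.ncol();
  LogicalMatrix mask(nr, nc);
  double *pz = REAL(z);
  int *pm = LOGICAL(mask);
  double *pb = REAL(b);
  for (int j = 0; j < nc; ++j) {
    double bj = pb[j];
    R_xlen_t off = (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double val = pz[off + i] + bj;
      bool pos = val > 0.0;
      pz[off + i] = pos ? val : 0.0;
      pm[off + i] = pos;
    }
  }
  return mask;
}

// Plain bias add in place (no rectifier), for output layers.
// [[Rcpp::export]]
void bias_add_(NumericMatrix z, NumericVector b) {
  int nr = z.nrow(), nc = z.ncol();
  double *pz = REAL(z);
  double *pb = REAL(b);
  for (int j = 0; j < nc; ++j) {
    double bj = pb[j];
    R_xlen_t off = (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) pz[off + i] += bj;
  }
}
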