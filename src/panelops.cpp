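// Small panel kernels used in the per-replicate estimation path.

#include <Rcpp.h>
using namespace Rcpp;

// Sum x by quarter index tq (1-based) onto a fixed grid 1..Tq.
// [[Rcpp::export(name = ".sum_by_q")]]
NumericVector sum_by_q(const NumericVector& x, const IntegerVector& tq,
                       const int Tq) {
  NumericVector out(Tq);
  const int n = x.size();
  for (int i = 0; i < n; ++i) out[tq[i] - 1] += x[i];
  return out;
}

// Cumulative product within contiguous groups (panel sorted by subject,
// quarter).  Exact zeros are absorbing.  With lag = true the result is
// shifted one position forward within each group (first element 1): the
// value carried into the next quarter.
// [[Rcpp::export(name = ".grp_cumprod")]]
NumericVector grp_cumprod_cpp(const NumericVector& x,
                              const IntegerVector& gstart, bool lag) {
  const int n = x.size();
  NumericVector out(n);
  int g = 0;
  const int ng = gstart.size();
  double acc = 1.0;
  for (int i = 0; i < n; ++i) {
    if (g < ng && i == gstart[g] - 1) { acc = 1.0; ++g; }
    if (lag) {
      out[i] = acc;
      acc *= x[i];
    } else {
      acc *= x[i];
      out[i] = acc;
    }
  }
  return out;
}
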