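// Fused per-replicate weight/hazard assembly.  These are straight O(n)
// passes over the panel; they exist because bootstrap inference runs them
// tens of thousands of times.

#include <Rcpp.h>
using namespace Rcpp;

// Censoring stabilization ratio per row: product over causes of
// (1 - marginal cause hazard at t) / max(1 - fitted cause hazard, floor).
// idx lists are 1-based row indices of each cause's risk set.
// [[Rcpp::export(name = ".censoring_ratio_cpp")]]
NumericVector censoring_ratio_cpp(const int n, const List idx_list,
                                  const List y_list, const List mu_list,
                                  const NumericVector& row_w,
                                  const IntegerVector& tq, const int Tq,
                                  const double floor_) {
  NumericVector ratio(n, 1.0);
  const int ncause = idx_list.size();
  std::vector<double> num(Tq), den(Tq);
  for (int c = 0; c < ncause; ++c) {
    IntegerVector idx = idx_list[c];
    NumericVector y = y_list[c];
    NumericVector mu = mu_list[c];
    const int m = idx.size();
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      const int r = idx[j] - 1;
      const double w = row_w[r];
      num[tq[r] - 1] += w * y[j];
      den[tq[r] - 1] += w;
    }
    for (int t = 0; t < Tq; ++t) {
      num[t] = den[t] > 0 ? 1.0 - num[t] / den[t] : 1.0;  // 1 - m_t
    }
    for (int j = 0; j < m; ++j) {
      const int r = idx[j] - 1;
      const double d = std::max(1.0 - mu[j], floor_);
      ratio[r] *= num[tq[r] - 1] / d;
    }
  }
  return ratio;
}

// One arm's weighted and crude hazard numerators/denominators in a single
// pass: cumulative treatment ratio within subject, combined with the
// lagged censoring component, truncated, multiplied by frequency weights,
// and summed by quarter.
// [[Rcpp::export(name = ".arm_hazard_cpp")]]
List arm_hazard_cpp(const NumericVector& ip, const NumericVector& p_obs,
                    const NumericVector& cw, const NumericVector& rw,
                    const NumericVector& event, const IntegerVector& tq,
                    const IntegerVector& gstart, const int Tq,
                    const double trunc_) {
  const int n = ip.size();
  NumericVector we(Tq), wr(Tq), ce(Tq), cr(Tq);
  int g = 0;
  const int ng = gstart.size();
  double acc = 1.0;
  for (int i = 0; i < n; ++i) {
    if (g < ng && i == gstart[g] - 1) { acc = 1.0; ++g; }
    acc *= ip[i] / p_obs[i];
    double w = acc * cw[i];
    if (w > trunc_) w = trunc_;
    const double f = rw[i];
    const int t = tq[i] - 1;
    we[t] += f * w * event[i];
    wr[t] += f * w;
    if (acc > 0) {   // crude: compatible person-quarters
      ce[t] += f * event[i];
      cr[t] += f;
    }
  }
  return List::create(Named("we") = we, Named("wr") = wr,
                      Named("ce") = ce, Named("cr") = cr);
}
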