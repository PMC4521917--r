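#include <Rcpp.h>
using namespace Rcpp;

// One sequential (online) training epoch over all presented rows.
// Weights are updated in place; returns the mean BMU distance measured at
// presentation time (a running quantization error for the epoch).
// [[Rcpp::export]]
double som_epoch_cpp(NumericMatrix weights, const NumericMatrix& data,
                     const IntegerVector& order, const NumericMatrix& coords,
                     double sigma, double eta) {
  const int m = weights.nrow(), k = weights.ncol(), n = order.size();
  const double s2 = 2.0 * sigma * sigma;
  double qe = 0.0;
  for (int t = 0; t < n; ++t) {
    const int i = order[t] - 1;
    int best = 0;
    double bd = R_PosInf;
    for (int node = 0; node < m; ++node) {
      double d = 0.0;
      for (int j = 0; j < k; ++j) {
        const double x = weights(node, j) - data(i, j);
        d += x * x;
      }
      if (d < bd) { bd = d; best = node; }
    }
    qe += std::sqrt(bd);
    const double bx = coords(best, 0), by = coords(best, 1);
    for (int node = 0; node < m; ++node) {
      const double dx = coords(node, 0) - bx, dy = coords(node, 1) - by;
      const double h = std::exp(-(dx * dx + dy * dy) / s2);
      if (h < 1e-7) continue;  // negligible update far from the BMU
      const double he = h * eta;
      for (int j = 0; j < k; ++j) {
        weights(node, j) += he * (data(i, j) - weights(node, j));
      }
    }
  }
  return qe / n;
}

// Best matching unit (1-based node index) for every row of x.
// Ties resolve to the smallest node index.
// [[Rcpp::export]]
IntegerVector bmu_batch_cpp(const NumericMatrix& weights,
                            const NumericMatrix& x) {
  const int m = weights.nrow(), k = weights.ncol(), n = x.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = R_PosInf;
    for (int node = 0; node < m; ++node) {
      double d = 0.0;
      for (int j = 0; j < k; ++j) {
        const double v = weights(node, j) - x(i, j);
        d += v * v;
      }
      if (d < bd) { bd = d; best = node; }
    }
    out[i] = best + 1;
  }
  return out;
}
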