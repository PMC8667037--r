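#include <Rcpp.h>
using namespace Rcpp;

// Unordered pairs (i < j) with minimum-image distance <= r on a periodic
// square domain of side L. Hot path of the diffusion-aggregation stepper.
// [[Rcpp::export(name = ".close_pairs")]]
IntegerMatrix close_pairs(NumericVector x, NumericVector y,
                          double L, double r) {
  const int n = x.size();
  const double r2 = r * r;
  const double hl = L / 2.0;
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = std::fabs(x[j] - xi);
      if (dx > hl) dx = L - dx;
      if (dx * dx > r2) continue;
      double dy = std::fabs(y[j] - yi);
      if (dy > hl) dy = L - dy;
      if (dx * dx + dy * dy <= r2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
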