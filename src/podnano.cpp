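#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Resampling engine for the Delta-L population deconvolution.
//
// Per resample: draw a bootstrap sample of events (with replacement),
// optionally jitter each drawn value by its reported standard error,
// accumulate the summed Gaussian-kernel density on a fixed grid
// (per-event kernel widths, truncated at +/- 5 sd), and record the
// positions of local maxima above a relative height threshold.
//
// Uses R's RNG so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List podnano_modes_cpp(NumericVector x, NumericVector kernel_sd,
                       NumericVector jitter_sd, int n_resamples,
                       double grid_lo, double grid_step, int grid_n,
                       double min_rel_height) {
  const int n = x.size();
  std::vector<double> dens(grid_n);
  std::vector<double> pos;
  std::vector<int> rid;
  pos.reserve(4 * n_resamples);
  rid.reserve(4 * n_resamples);

  for (int r = 0; r < n_resamples; ++r) {
    std::fill(dens.begin(), dens.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      double v = x[i];
      if (jitter_sd[i] > 0.0) v += norm_rand() * jitter_sd[i];
      const double s = kernel_sd[i];
      int a = (int)std::floor((v - 5.0 * s - grid_lo) / grid_step);
      int b = (int)std::ceil((v + 5.0 * s - grid_lo) / grid_step);
      if (a < 0) a = 0;
      if (b > grid_n - 1) b = grid_n - 1;
      for (int g = a; g <= b; ++g) {
        const double z = (grid_lo + g * grid_step - v) / s;
        dens[g] += std::exp(-0.5 * z * z) / s;
      }
    }
    double dmax = 0.0;
    for (int g = 0; g < grid_n; ++g)
      if (dens[g] > dmax) dmax = dens[g];
    const double thr = dmax * min_rel_height;
    for (int g = 1; g < grid_n - 1; ++g) {
      if (dens[g] >= thr && dens[g] > dens[g - 1] && dens[g] >= dens[g + 1]) {
        pos.push_back(grid_lo + g * grid_step);
        rid.push_back(r + 1);
      }
    }
  }
  return List::create(_["position"] = wrap(pos), _["resample"] = wrap(rid));
}
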