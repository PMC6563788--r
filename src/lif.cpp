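#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Sequential threshold scan of a current-based LIF neuron on the time grid.
//
// u        input-driven potential (weights x PSP table) at each grid time
// theta    firing threshold (mV)
// decay    exp(-dt/tau_m), decay factor of the post-spike reset kernel
// stop_idx 1-based last grid index to evaluate; <= 0 means the full trace
// noise    optional additive per-step term (length 0, or >= stop index)
//
// The reset sum theta * sum_{ts < t} exp(-(t - ts)/tau_m) is carried as a
// single accumulator: r(t) = (r(t - dt) + theta * spiked(t - dt)) * decay,
// so a spike at t lowers the potential strictly after t only.
// [[Rcpp::export(name = ".lif_scan")]]
List lif_scan(NumericVector u, double theta, double decay, int stop_idx,
              NumericVector noise) {
  const int n = u.size();
  const int last = (stop_idx > 0 && stop_idx <= n) ? stop_idx : n;
  const bool has_noise = noise.size() >= last && noise.size() > 0;
  NumericVector v(last);
  std::vector<int> sp;
  double r = 0.0;
  bool prev = false;
  for (int t = 0; t < last; ++t) {
    r = (r + (prev ? theta : 0.0)) * decay;
    double vt = u[t] - r;
    if (has_noise) vt += noise[t];
    v[t] = vt;
    prev = vt >= theta;
    if (prev) sp.push_back(t + 1);  // 1-based grid index
  }
  return List::create(_["v"] = v, _["spike_idx"] = wrap(sp));
}

// Superposition of identical symmetric profiles centred at given grid
// indices: out[t] = sum_j g[|t - idx_j|], with g tabulated for lags
// 0 .. n-1. Used for exact Gaussian filtering of spike trains.
// [[Rcpp::export(name = ".profile_sum")]]
NumericVector profile_sum(IntegerVector idx, NumericVector g, int n) {
  NumericVector v(n);
  for (int j = 0; j < idx.size(); ++j) {
    const int k = idx[j] - 1;
    for (int t = 0; t < n; ++t) v[t] += g[std::abs(t - k)];
  }
  return v;
}
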