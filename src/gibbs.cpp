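#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a pairwise maximum-entropy (Ising, {0,1} spins) model:
//   P(s) = exp(sum_i h_i s_i + 0.5 * sum_{i!=j} J_ij s_i s_j) / Z.
// One retained column per `thin` full sweeps after `burn_in` sweeps.
// Uses R's RNG so set.seed() governs the draw.
// [[Rcpp::export]]
IntegerMatrix gibbs_ising(NumericVector h, NumericMatrix J, int n_bins,
                          int burn_in, int thin) {
  const int n = h.size();
  std::vector<int> s(n, 0);
  IntegerMatrix out(n, n_bins);
  RNGScope scope;

  // random start
  for (int i = 0; i < n; ++i) s[i] = unif_rand() < 0.5 ? 1 : 0;

  auto sweep = [&]() {
    for (int i = 0; i < n; ++i) {
      double field = h[i];
      for (int j = 0; j < n; ++j)
        if (j != i && s[j]) field += J(i, j);
      double p1 = 1.0 / (1.0 + std::exp(-field));
      s[i] = unif_rand() < p1 ? 1 : 0;
    }
  };

  for (int b = 0; b < burn_in; ++b) sweep();
  for (int t = 0; t < n_bins; ++t) {
    for (int k = 0; k < thin; ++k) sweep();
    for (int i = 0; i < n; ++i) out(i, t) = s[i];
  }
  return out;
}
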