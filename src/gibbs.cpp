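#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the pairwise {-1,+1} observation model
// p(x | w) propto exp( sum_{e=(i,j)} w_e x_i x_j ).
//
// The graph is passed in compressed adjacency form: ptr is a 0-based offset
// vector of length n+1, nbr[ptr[i]..ptr[i+1]-1] are the neighbours of node i
// and wt holds the (possibly damped, real-valued) edge weight attached to
// each adjacency entry. Sites are updated in fixed order 0..n-1; the
// conditional is p(x_i = +1 | rest) = 1 / (1 + exp(-2 * sum_j w_ij x_j)).
// Uses R's RNG so results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerMatrix ising_gibbs_chain(IntegerVector ptr, IntegerVector nbr,
                                NumericVector wt, IntegerVector x0,
                                int n_burn, int n_keep, int thin) {
  const int n = x0.size();
  if (n_keep < 1) stop("n_keep must be >= 1");
  if (thin < 1) stop("thin must be >= 1");
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix out(n_keep, n);

  auto sweep = [&]() {
    for (int i = 0; i < n; ++i) {
      double field = 0.0;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k)
        field += wt[k] * x[nbr[k]];
      const double p = 1.0 / (1.0 + std::exp(-2.0 * field));
      x[i] = (unif_rand() < p) ? 1 : -1;
    }
  };

  for (int b = 0; b < n_burn; ++b) sweep();
  for (int s = 0; s < n_keep; ++s) {
    for (int t = 0; t < thin; ++t) sweep();
    for (int i = 0; i < n; ++i) out(s, i) = x[i];
  }
  return out;
}
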