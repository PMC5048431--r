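#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sweep for the network (Ising) form.  Full conditional:
// p(x_i = +1 | rest) = logistic(2 * (delta_i + sum_{j != i} sigma_ij x_j)).
// Systematic site scan; uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_ising_cpp(NumericVector delta, NumericMatrix sigma,
                              int n_keep, int burnin, int thin,
                              IntegerVector x0) {
  int n = delta.size();
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix out(n_keep, n);
  int total_sweeps = burnin + n_keep * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total_sweeps; sweep++) {
    for (int i = 0; i < n; i++) {
      double field = delta[i];
      for (int j = 0; j < n; j++) field += sigma(i, j) * x[j];
      double p = 1.0 / (1.0 + std::exp(-2.0 * field));
      x[i] = (unif_rand() < p) ? 1 : -1;
    }
    if (sweep >= burnin && (sweep - burnin) % thin == 0) {
      for (int i = 0; i < n; i++) out(kept, i) = x[i];
      kept++;
    }
  }
  return out;
}

// Data-augmentation Gibbs for the latent (MIRT) form.  Alternates
//   theta | x ~ Normal(A' x, I)   (exact Gaussian)
//   x | theta: independent items, p(x_i = +1) = logistic(2 * eta_i),
//              eta_i = delta_i + a_i' theta.
// [[Rcpp::export]]
List gibbs_augmented_cpp(NumericVector delta, NumericMatrix a_matrix,
                         int n_keep, int burnin, int thin, IntegerVector x0) {
  int n = delta.size();
  int m = a_matrix.ncol();
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> theta(m, 0.0);
  IntegerMatrix xout(n_keep, n);
  NumericMatrix tout(n_keep, m);
  int total_sweeps = burnin + n_keep * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total_sweeps; sweep++) {
    for (int r = 0; r < m; r++) {
      double mu = 0.0;
      for (int i = 0; i < n; i++) mu += a_matrix(i, r) * x[i];
      theta[r] = mu + norm_rand();
    }
    for (int i = 0; i < n; i++) {
      double eta = delta[i];
      for (int r = 0; r < m; r++) eta += a_matrix(i, r) * theta[r];
      double p = 1.0 / (1.0 + std::exp(-2.0 * eta));
      x[i] = (unif_rand() < p) ? 1 : -1;
    }
    if (sweep >= burnin && (sweep - burnin) % thin == 0) {
      for (int i = 0; i < n; i++) xout(kept, i) = x[i];
      for (int r = 0; r < m; r++) tout(kept, r) = theta[r];
      kept++;
    }
  }
  return List::create(_["draws"] = xout, _["latent_draws"] = tout);
}
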