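#include <Rcpp.h>
using namespace Rcpp;

// Threshold-Gaussian haplotype sampler.
//
// For haplotype h of individual i, the latent variable at variant j is
//   sqrt(rho) * U[i, block_j, h] + sqrt(1 - rho) * e_ijh,
// with U and e standard normal, so variants in the same block share latent
// correlation rho. The haplotype carries the coded allele when the latent
// variable exceeds thr_j = qnorm(1 - f_j); the dosage is the sum over the
// two haplotypes. Uses R's RNG, so results are reproducible under set.seed.
//
// block: 0-based block index per variant; thr: per-variant threshold.
// [[Rcpp::export]]
IntegerMatrix sample_block_dosages(int n, IntegerVector block,
                                   NumericVector thr, double rho) {
  const int m = block.size();
  int n_blocks = 0;
  for (int j = 0; j < m; ++j) {
    if (block[j] + 1 > n_blocks) n_blocks = block[j] + 1;
  }
  const double sr = std::sqrt(rho), se = std::sqrt(1.0 - rho);
  IntegerMatrix dos(n, m);
  std::vector<double> U(static_cast<size_t>(n) * n_blocks);

  for (int h = 0; h < 2; ++h) {
    for (size_t k = 0; k < U.size(); ++k) U[k] = norm_rand();
    for (int j = 0; j < m; ++j) {
      const double t = thr[j];
      const double* ub = &U[static_cast<size_t>(block[j]) * n];
      int* col = &dos(0, j);
      if (rho > 0.0) {
        for (int i = 0; i < n; ++i) {
          if (se * norm_rand() + sr * ub[i] > t) col[i] += 1;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          if (norm_rand() > t) col[i] += 1;
        }
      }
    }
  }
  return dos;
}
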