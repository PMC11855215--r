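#include <Rcpp.h>
using namespace Rcpp;

// Haplotype-copy mosaic genotype simulator.
//
// Two independent haplotypes per sample. Along a block, each haplotype's
// allele copies the previous variant's allele with probability rho and is
// otherwise drawn fresh at that variant's allele frequency; blocks are
// independent. A single uniform per cell decides both the copy event and,
// conditionally, the fresh draw: given u >= rho, (u - rho) / (1 - rho) is
// uniform, so "fresh carrier" is u < rho + (1 - rho) * maf.
//
// Uses R's RNG stream, so results are reproducible under set.seed().

// [[Rcpp::export(name = ".sim_mosaic_dosage")]]
IntegerMatrix sim_mosaic_dosage(int n, NumericVector maf, IntegerVector block,
                                double rho) {
  const int m = maf.size();
  IntegerMatrix G(n, m);
  std::vector<char> prev1(n), prev2(n);
  for (int j = 0; j < m; ++j) {
    const double p = maf[j];
    const bool linked = j > 0 && block[j] == block[j - 1] && rho > 0.0;
    const double thr = rho + (1.0 - rho) * p;
    int *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      char h1, h2;
      if (linked) {
        double u1 = unif_rand();
        h1 = (u1 < rho) ? prev1[i] : (char)(u1 < thr);
        double u2 = unif_rand();
        h2 = (u2 < rho) ? prev2[i] : (char)(u2 < thr);
      } else {
        h1 = (char)(unif_rand() < p);
        h2 = (char)(unif_rand() < p);
      }
      prev1[i] = h1;
      prev2[i] = h2;
      col[i] = h1 + h2;
    }
  }
  return G;
}
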