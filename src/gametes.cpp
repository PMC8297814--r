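#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Meiosis kernel shared by the forward simulator and the pedigree gene
// drop. Haplotypes are stored site-major (m sites x n haplotypes) so the
// per-site walk streams down contiguous columns. For each gamete: per
// chromosome, crossover count ~ Poisson(length_bp / 1e8 * factor),
// uniform crossover positions, random start phase; sites take the
// haplotype implied by the crossover count to their left. Uses R's RNG
// so results respect set.seed().
//
// H:        (m x n_hap) 0/1 haplotype matrix, sites in rows
// parents:  (n_gametes x 2) 1-based column indices of the two parental
//           haplotypes
// pos:      site positions in bp (sorted within chromosome)
// chrom_start, chrom_end: 1-based inclusive site index range per chromosome
// len_bp:   chromosome lengths in bp
// factor:   multiplier on the 1-per-100-Mb crossover rate

// [[Rcpp::export]]
IntegerMatrix gametes_cpp(const IntegerMatrix& H, const IntegerMatrix& parents,
                          const NumericVector& pos,
                          const IntegerVector& chrom_start,
                          const IntegerVector& chrom_end,
                          const NumericVector& len_bp, double factor) {
  const int ng = parents.nrow();
  const int m = pos.size();
  const int nc = chrom_start.size();
  IntegerMatrix out(m, ng);
  std::vector<double> xo;
  for (int g = 0; g < ng; ++g) {
    const int* h1 = &H(0, parents(g, 0) - 1);
    const int* h2 = &H(0, parents(g, 1) - 1);
    int* o = &out(0, g);
    for (int c = 0; c < nc; ++c) {
      const int lo = chrom_start[c] - 1;
      const int hi = chrom_end[c] - 1;
      const double lambda = len_bp[c] / 1e8 * factor;
      const int k = (lambda > 0) ? (int) R::rpois(lambda) : 0;
      int src = (R::unif_rand() < 0.5) ? 0 : 1;
      if (k == 0) {
        const int* h = (src == 0) ? h1 : h2;
        for (int i = lo; i <= hi; ++i) o[i] = h[i];
      } else {
        xo.resize(k);
        for (int j = 0; j < k; ++j) xo[j] = R::unif_rand() * len_bp[c];
        std::sort(xo.begin(), xo.end());
        int j = 0;
        for (int i = lo; i <= hi; ++i) {
          while (j < k && xo[j] < pos[i]) { ++j; src ^= 1; }
          o[i] = (src == 0) ? h1[i] : h2[i];
        }
      }
    }
  }
  return out;
}
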