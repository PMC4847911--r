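#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Conditional null of the HWE tests: the observed multiset of gene copies is
// shuffled and re-paired, i.e. genotype tables are drawn uniformly from all
// pairings with the observed allele counts.  For each replicate we return
//   col 0: the table-dependent part of the log conditional probability,
//          H*log(2) - sum_g lgamma(n_g + 1)   (terms fixed by the allele
//          counts cancel when comparing tables),
//   col 1: the homozygote score sum over homozygous individuals of
//          w[allele] (w = 1 gives the plain homozygote count).
// Uses R's RNG, so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
NumericMatrix hweNullSim(IntegerVector copies, int nMc, NumericVector w) {
  int m = copies.size(); // 2n gene copies, allele codes 1..A
  int n = m / 2;
  std::vector<int> v(copies.begin(), copies.end());
  NumericMatrix out(nMc, 2);
  std::unordered_map<long long, int> counts;
  counts.reserve(n * 2);
  double l2 = std::log(2.0);
  for (int rep = 0; rep < nMc; ++rep) {
    for (int i = m - 1; i > 0; --i) { // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    counts.clear();
    double U = 0.0;
    int H = 0;
    for (int i = 0; i < n; ++i) {
      int a = v[2 * i], b = v[2 * i + 1];
      if (a > b) std::swap(a, b);
      if (a == b) U += w[a - 1]; else ++H;
      ++counts[(long long)a * 1000000LL + b];
    }
    double lp = H * l2;
    for (std::unordered_map<long long, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
      lp -= R::lgammafn(it->second + 1.0);
    out(rep, 0) = lp;
    out(rep, 1) = U;
  }
  return out;
}
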