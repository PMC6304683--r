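#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-in-time diploid Wright-Fisher simulator with crossover
// recombination, used to produce SNP panels that carry realistic linkage
// disequilibrium (the backward simulator treats loci as unlinked).
//
// founders: haplotype matrix, rows = 2*N0 haplotypes, cols = M biallelic
//           sites coded 0/1. Random mating, discrete generations; diploid
//           size in generation g is N_per_gen[g]. Crossovers are Poisson on
//           the genetic map (pos_morgans within each chromosome), with a
//           fair-coin starting phase per gamete per chromosome.

// [[Rcpp::export(name = ".sim_wf_cpp")]]
IntegerMatrix sim_wf_cpp(IntegerMatrix founders,
                         NumericVector pos_morgans,
                         IntegerVector chrom_id,
                         IntegerVector N_per_gen,
                         double mut_rate) {
  const int M = founders.ncol();
  if (pos_morgans.size() != M || chrom_id.size() != M)
    stop("positions/chromosome vectors must match the marker count");
  const int H0 = founders.nrow();
  if (H0 < 2 || H0 % 2 != 0) stop("founders must hold an even number of haplotypes");

  // chromosome block boundaries (markers assumed grouped & sorted upstream)
  std::vector<int> cstart, cend;  // [start, end) per chromosome block
  for (int j = 0; j < M; ++j) {
    if (j == 0 || chrom_id[j] != chrom_id[j - 1]) cstart.push_back(j);
    if (j == M - 1 || chrom_id[j] != chrom_id[j + 1]) cend.push_back(j + 1);
  }
  const int n_chr = (int)cstart.size();

  std::vector<uint8_t> cur((size_t)H0 * M), nxt;
  for (int i = 0; i < H0; ++i)
    for (int j = 0; j < M; ++j) cur[(size_t)i * M + j] = (uint8_t)founders(i, j);
  int N_prev = H0 / 2;

  std::vector<double> xo;
  const int n_gen = N_per_gen.size();
  for (int g = 0; g < n_gen; ++g) {
    const int N = N_per_gen[g];
    if (N < 1) stop("population size must be >= 1");
    nxt.assign((size_t)2 * N * M, 0);
    for (int i = 0; i < N; ++i) {
      for (int par = 0; par < 2; ++par) {
        int pidx = (int)(unif_rand() * N_prev);
        if (pidx >= N_prev) pidx = N_prev - 1;
        const uint8_t *h0 = &cur[(size_t)(2 * pidx) * M];
        const uint8_t *h1 = &cur[(size_t)(2 * pidx + 1) * M];
        uint8_t *dst = &nxt[(size_t)(2 * i + par) * M];
        for (int c = 0; c < n_chr; ++c) {
          const int s = cstart[c], e = cend[c];
          const double len = pos_morgans[e - 1] - pos_morgans[s];
          int nxo = (len > 0) ? (int)R::rpois(len) : 0;
          int phase = (unif_rand() < 0.5) ? 0 : 1;
          if (nxo == 0) {
            const uint8_t *src = phase ? h1 : h0;
            std::copy(src + s, src + e, dst + s);
          } else {
            xo.clear();
            for (int x = 0; x < nxo; ++x)
              xo.push_back(pos_morgans[s] + unif_rand() * len);
            std::sort(xo.begin(), xo.end());
            size_t xi = 0;
            for (int j = s; j < e; ++j) {
              while (xi < xo.size() && pos_morgans[j] > xo[xi]) { phase ^= 1; ++xi; }
              dst[j] = phase ? h1[j] : h0[j];
            }
          }
        }
        if (mut_rate > 0.0) {
          for (int j = 0; j < M; ++j)
            if (unif_rand() < mut_rate) dst[j] ^= 1;
        }
      }
    }
    cur.swap(nxt);
    N_prev = N;
  }

  IntegerMatrix out(2 * N_prev, M);
  for (int i = 0; i < 2 * N_prev; ++i)
    for (int j = 0; j < M; ++j) out(i, j) = cur[(size_t)i * M + j];
  return out;
}
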