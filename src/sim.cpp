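#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Wright-Fisher gamete formation with Poisson crossovers (Haldane map:
// expected chrom_len/100 crossovers per meiosis per chromosome, no
// interference).  Haplotypes are stored loci-by-haplotypes (L x 2N, one
// column per haplotype, columns 2i and 2i+1 belonging to individual i) so
// that copying a gamete walks contiguous memory.  Loci are sorted by
// (chr, pos).  All randomness goes through R's RNG so set.seed() governs
// everything.

static void make_gamete(const IntegerMatrix &hap, int parent,
                        const NumericVector &pos,
                        const IntegerVector &chr_start,
                        const IntegerVector &chr_end,
                        const NumericVector &chr_lo,
                        const NumericVector &chr_len,
                        int *out) {
  const int n_chr = chr_start.size();
  std::vector<double> xo;
  const int *h0 = &hap(0, 2 * parent);
  const int *h1 = &hap(0, 2 * parent + 1);
  const int *strands[2] = {h0, h1};
  for (int c = 0; c < n_chr; ++c) {
    const int s = chr_start[c], e = chr_end[c]; // [s, e)
    int strand = (unif_rand() < 0.5) ? 1 : 0;
    const int k = (int)R::rpois(chr_len[c] / 100.0);
    if (k == 0) {
      const int *src = strands[strand];
      for (int j = s; j < e; ++j) out[j] = src[j];
      continue;
    }
    xo.resize(k);
    for (int i = 0; i < k; ++i)
      xo[i] = chr_lo[c] + unif_rand() * chr_len[c];
    std::sort(xo.begin(), xo.end());
    int xi = 0;
    for (int j = s; j < e; ++j) {
      while (xi < k && xo[xi] < pos[j]) { strand ^= 1; ++xi; }
      out[j] = strands[strand][j];
    }
  }
}

// Advance one generation: n_off offspring, each from two distinct parents
// drawn uniformly from `parents` (0-based individual indices).
// [[Rcpp::export]]
IntegerMatrix wf_generation(const IntegerMatrix &hap,
                            const IntegerVector &parents, int n_off,
                            const NumericVector &pos,
                            const IntegerVector &chr_start,
                            const IntegerVector &chr_end,
                            const NumericVector &chr_lo,
                            const NumericVector &chr_len) {
  const int L = hap.nrow();
  const int np = parents.size();
  if (np < 2) stop("need at least 2 parents");
  IntegerMatrix off(L, 2 * n_off);
  for (int i = 0; i < n_off; ++i) {
    int p1 = parents[(int)(unif_rand() * np) % np];
    int p2 = p1;
    while (p2 == p1) p2 = parents[(int)(unif_rand() * np) % np];
    make_gamete(hap, p1, pos, chr_start, chr_end, chr_lo, chr_len,
                &off(0, 2 * i));
    make_gamete(hap, p2, pos, chr_start, chr_end, chr_lo, chr_len,
                &off(0, 2 * i + 1));
  }
  return off;
}

// Collapse an L x 2N haplotype matrix to an N x L dosage matrix
// (individuals in rows, to match the analysis layout).
// [[Rcpp::export]]
NumericMatrix hap_dosages(const IntegerMatrix &hap) {
  const int L = hap.nrow(), n = hap.ncol() / 2;
  NumericMatrix d(n, L);
  for (int i = 0; i < n; ++i) {
    const int *a = &hap(0, 2 * i);
    const int *b = &hap(0, 2 * i + 1);
    double *row = &d(i, 0);
    for (int j = 0; j < L; ++j) row[j * n] = a[j] + b[j];
  }
  return d;
}
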