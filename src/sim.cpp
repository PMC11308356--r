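#include <Rcpp.h>
using namespace Rcpp;

// Build one recombinant gamete into out[]. Crossover count per chromosome
// is Poisson(length_bp * rate) with uniform breakpoint placement (Haldane
// model, no interference); the starting haplotype of each chromosome is
// chosen at random. Uses the R RNG, so results are reproducible under
// set.seed().
static void meiosis_raw(const int* h1, const int* h2, const int* cfirst,
                        const int* clast, int nchr, const double* pos,
                        double rate, int* out) {
  for (int c = 0; c < nchr; ++c) {
    int a = cfirst[c] - 1, b = clast[c] - 1;
    double len = pos[b] - pos[a];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int k = (len > 0 && rate > 0) ? (int) R::rpois(len * rate) : 0;
    if (k == 0) {
      const int* src = cur ? h2 : h1;
      for (int j = a; j <= b; ++j) out[j] = src[j];
      continue;
    }
    std::vector<double> bp(k);
    for (int i = 0; i < k; ++i) bp[i] = pos[a] + unif_rand() * len;
    std::sort(bp.begin(), bp.end());
    int bi = 0;
    for (int j = a; j <= b; ++j) {
      while (bi < k && bp[bi] <= pos[j]) { cur = 1 - cur; ++bi; }
      out[j] = cur ? h2[j] : h1[j];
    }
  }
}

// One meiosis: recombinant mosaic of the two parental haplotype vectors
// (any integer payload: allele states or founder-haplotype ids).
// chrom_first/chrom_last: 1-based index of each chromosome's first/last
// SNP; pos: bp positions.
// [[Rcpp::export]]
IntegerVector meiosis_cpp(const IntegerVector& h1, const IntegerVector& h2,
                          const IntegerVector& chrom_first,
                          const IntegerVector& chrom_last,
                          const NumericVector& pos, double rate) {
  IntegerVector out(h1.size());
  meiosis_raw(h1.begin(), h2.begin(), chrom_first.begin(),
              chrom_last.begin(), chrom_first.size(), pos.begin(), rate,
              out.begin());
  return out;
}

// Advance a Wright-Fisher population n_gen generations of random mating
// with replacement (monoecious, selfing allowed) and meiosis as above.
// haps: m x 2N matrix, individual i owning columns 2i, 2i+1 (0-based).
// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix haps,
                            const IntegerVector& chrom_first,
                            const IntegerVector& chrom_last,
                            const NumericVector& pos, double rate,
                            int n_gen) {
  int m = haps.nrow();
  int N = haps.ncol() / 2;
  int nchr = chrom_first.size();
  std::vector<int> cur(haps.begin(), haps.end());
  std::vector<int> nxt(cur.size());
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < N; ++i) {
      for (int side = 0; side < 2; ++side) {
        int par = (int) (unif_rand() * N);
        if (par == N) par = N - 1;
        meiosis_raw(&cur[(size_t) m * (2 * par)],
                    &cur[(size_t) m * (2 * par + 1)],
                    chrom_first.begin(), chrom_last.begin(), nchr,
                    pos.begin(), rate, &nxt[(size_t) m * (2 * i + side)]);
      }
    }
    cur.swap(nxt);
  }
  IntegerMatrix res(m, 2 * N);
  std::copy(cur.begin(), cur.end(), res.begin());
  return res;
}
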