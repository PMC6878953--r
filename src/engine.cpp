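#include <Rcpp.h>
using namespace Rcpp;

// Gamete formation under the Haldane model: per chromosome the crossover
// count is Poisson with mean equal to the chromosome's genetic length
// (Morgans), crossover positions are uniform on the genetic scale, the
// starting strand is chosen with probability 1/2, and chromosomes
// assort independently. Uses R's RNG so results are reproducible with
// set.seed().
//
// A, B:        parent's two haplotypes (length n_loci)
// out:         gamete destination
// chrom_start: 0-based first locus index of each chromosome, plus n_loci
//              as a final sentinel (length n_chrom + 1)
// gpos:        per-locus genetic position in Morgans within its chromosome
// glen:        per-chromosome genetic length in Morgans
static void gamete_into(const int* A, const int* B, int* out,
                        const IntegerVector& chrom_start,
                        const NumericVector& gpos,
                        const NumericVector& glen) {
  const int n_chrom = glen.size();
  std::vector<double> xpos;
  for (int c = 0; c < n_chrom; ++c) {
    const int lo = chrom_start[c], hi = chrom_start[c + 1];
    int strand = (unif_rand() < 0.5) ? 1 : 0;
    int nx = 0;
    if (glen[c] > 0.0) nx = (int) R::rpois(glen[c]);
    if (nx == 0 || lo == hi) {
      const int* src = strand ? B : A;
      std::copy(src + lo, src + hi, out + lo);
      continue;
    }
    xpos.resize(nx);
    for (int i = 0; i < nx; ++i) xpos[i] = unif_rand() * glen[c];
    std::sort(xpos.begin(), xpos.end());
    // copy segment-wise: a crossover at genetic position x moves loci with
    // gpos >= x onto the switched strand
    int l = lo;
    for (int xi = 0; xi <= nx; ++xi) {
      const double upper = (xi < nx) ? xpos[xi] : R_PosInf;
      int l2 = l;
      while (l2 < hi && gpos[l2] < upper) ++l2;
      const int* src = strand ? B : A;
      std::copy(src + l, src + l2, out + l);
      l = l2;
      strand ^= 1;
      if (l == hi) break;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(IntegerMatrix individual, int n,
                               IntegerVector chrom_start,
                               NumericVector gpos, NumericVector glen) {
  const int n_loci = individual.nrow();
  if (individual.ncol() != 2)
    stop("an individual must have exactly two haplotypes");
  IntegerMatrix out(n_loci, n);
  const int* A = individual.begin();
  const int* B = individual.begin() + n_loci;
  for (int j = 0; j < n; ++j)
    gamete_into(A, B, out.begin() + (R_xlen_t) j * n_loci,
                chrom_start, gpos, glen);
  return out;
}

// Produce the next generation: offspring j receives one gamete from
// individual p1[j] and one from individual p2[j] (1-based indices into
// the current population). haps holds two adjacent columns per
// individual.
// [[Rcpp::export]]
IntegerMatrix cpp_next_generation(IntegerMatrix haps,
                                  IntegerVector p1, IntegerVector p2,
                                  IntegerVector chrom_start,
                                  NumericVector gpos, NumericVector glen) {
  const int n_loci = haps.nrow();
  const int n_off = p1.size();
  if (p2.size() != n_off) stop("parent vectors differ in length");
  IntegerMatrix out(n_loci, 2 * n_off);
  const int* base = haps.begin();
  int* obase = out.begin();
  for (int j = 0; j < n_off; ++j) {
    const int* A1 = base + (R_xlen_t)(2 * (p1[j] - 1)) * n_loci;
    const int* A2 = base + (R_xlen_t)(2 * (p2[j] - 1)) * n_loci;
    gamete_into(A1, A1 + n_loci, obase + (R_xlen_t)(2 * j) * n_loci,
                chrom_start, gpos, glen);
    gamete_into(A2, A2 + n_loci, obase + (R_xlen_t)(2 * j + 1) * n_loci,
                chrom_start, gpos, glen);
  }
  return out;
}

// Derived-allele counts per locus (row sums over haplotype columns).
// [[Rcpp::export]]
IntegerVector cpp_allele_counts(IntegerMatrix haps) {
  const int n_loci = haps.nrow(), n_h = haps.ncol();
  IntegerVector out(n_loci);
  const int* p = haps.begin();
  for (int h = 0; h < n_h; ++h) {
    int* o = out.begin();
    for (int l = 0; l < n_loci; ++l) *o++ += *p++;
  }
  return out;
}
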