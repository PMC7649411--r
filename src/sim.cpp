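#include <Rcpp.h>
#include <set>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Haplotype layout: RawMatrix with one row per locus and two columns per
// individual (column 2i = paternally inherited haplotype of individual i,
// 2i+1 = maternally inherited).  Loci are ordered by chromosome, with
// chrom_start giving 0-based locus offsets (length n_chrom + 1) and pos the
// genetic position (cM) of each locus within its chromosome.

namespace {

// One gamete from parent haplotype columns h0/h1 into dest, then recurrent
// mutation at rate mu per locus.  Haldane model: crossover count per
// chromosome ~ Poisson(length in Morgans), breakpoints uniform.
void make_gamete(Rbyte *dest, const Rbyte *h0, const Rbyte *h1,
                 const int *chrom_start, int n_chrom,
                 const double *pos, const double *chrom_len,
                 const int *n_alleles, int n_loci, double mu,
                 std::vector<double> &breaks) {
  for (int c = 0; c < n_chrom; ++c) {
    int lo = chrom_start[c], hi = chrom_start[c + 1];
    int k = (int) R::rpois(chrom_len[c] / 100.0);
    breaks.clear();
    for (int b = 0; b < k; ++b) breaks.push_back(unif_rand() * chrom_len[c]);
    std::sort(breaks.begin(), breaks.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    const Rbyte *src[2] = {h0, h1};
    // copy whole segments between consecutive breakpoints
    int j = lo;
    for (size_t bp = 0; bp < breaks.size() && j < hi; ++bp) {
      const double *seg_end = std::upper_bound(pos + j, pos + hi, breaks[bp]);
      int je = (int) (seg_end - pos);
      if (je > j) memcpy(dest + j, src[cur] + j, je - j);
      j = je;
      cur ^= 1;
    }
    if (j < hi) memcpy(dest + j, src[cur] + j, hi - j);
  }
  if (mu > 0) {
    int nm = (int) R::rpois(mu * n_loci);
    for (int m = 0; m < nm; ++m) {
      int j = (int) (unif_rand() * n_loci);
      if (j >= n_loci) j = n_loci - 1;
      int na = n_alleles[j];
      if (na < 2) continue;
      int a = dest[j];
      int b = (int) (unif_rand() * (na - 1));
      if (b >= a) ++b;
      dest[j] = (Rbyte) b;
    }
  }
}

} // namespace

// Random-union-of-gametes generations: gen_sizes[t] individuals per
// generation, each drawing two distinct parents uniformly from the previous
// generation.  Returns the final generation's haplotypes.
// [[Rcpp::export]]
RawMatrix cpp_historical(RawMatrix founders, IntegerVector gen_sizes,
                         IntegerVector chrom_start, NumericVector pos,
                         NumericVector chrom_len, IntegerVector n_alleles,
                         double mu) {
  int n_loci = founders.nrow();
  int n_chrom = chrom_len.size();
  std::vector<double> breaks;
  RawMatrix cur = founders;
  int n_prev = founders.ncol() / 2;
  for (int t = 0; t < gen_sizes.size(); ++t) {
    int n = gen_sizes[t];
    if (n_prev < 2) stop("need at least 2 parents per generation");
    RawMatrix nxt(n_loci, 2 * n);
    for (int i = 0; i < n; ++i) {
      int p1 = (int) (unif_rand() * n_prev); if (p1 >= n_prev) p1 = n_prev - 1;
      int p2 = p1;
      while (p2 == p1) {
        p2 = (int) (unif_rand() * n_prev); if (p2 >= n_prev) p2 = n_prev - 1;
      }
      make_gamete(&nxt(0, 2 * i), &cur(0, 2 * p1), &cur(0, 2 * p1 + 1),
                  chrom_start.begin(), n_chrom, pos.begin(), chrom_len.begin(),
                  n_alleles.begin(), n_loci, mu, breaks);
      make_gamete(&nxt(0, 2 * i + 1), &cur(0, 2 * p2), &cur(0, 2 * p2 + 1),
                  chrom_start.begin(), n_chrom, pos.begin(), chrom_len.begin(),
                  n_alleles.begin(), n_loci, mu, breaks);
    }
    cur = nxt;
    n_prev = n;
    if (t % 100 == 0) Rcpp::checkUserInterrupt();
  }
  return cur;
}

// Drop gametes for a batch of offspring whose parents are individuals of
// `haps` (0-based indices).  Offspring o is written into columns
// 2*(out_start + o) (sire gamete) and 2*(out_start + o)+1 (dam gamete) of
// `out`, in place.  `out` may be the same matrix as `haps` provided parent
// columns precede offspring columns.
// [[Rcpp::export]]
void cpp_drop(RawMatrix haps, RawMatrix out, int out_start,
              IntegerVector sire_idx, IntegerVector dam_idx,
              IntegerVector chrom_start, NumericVector pos,
              NumericVector chrom_len, IntegerVector n_alleles, double mu) {
  int n_loci = haps.nrow();
  if (out.nrow() != n_loci) stop("locus dimension mismatch");
  int n_chrom = chrom_len.size();
  std::vector<double> breaks;
  for (int o = 0; o < sire_idx.size(); ++o) {
    int s = sire_idx[o], d = dam_idx[o];
    int oc = 2 * (out_start + o);
    make_gamete(&out(0, oc), &haps(0, 2 * s), &haps(0, 2 * s + 1),
                chrom_start.begin(), n_chrom, pos.begin(), chrom_len.begin(),
                n_alleles.begin(), n_loci, mu, breaks);
    make_gamete(&out(0, oc + 1), &haps(0, 2 * d), &haps(0, 2 * d + 1),
                chrom_start.begin(), n_chrom, pos.begin(), chrom_len.begin(),
                n_alleles.begin(), n_loci, mu, breaks);
  }
}

// Dosage of allele 1 (the "second" allele) for a subset of individuals and
// loci; rows = individuals, columns = loci.
// [[Rcpp::export]]
IntegerMatrix cpp_dosages(RawMatrix haps, IntegerVector ind_idx,
                          IntegerVector locus_idx) {
  int n = ind_idx.size(), m = locus_idx.size();
  IntegerMatrix M(n, m);
  for (int j = 0; j < m; ++j) {
    int l = locus_idx[j];
    for (int i = 0; i < n; ++i) {
      int c = 2 * ind_idx[i];
      M(i, j) = (haps(l, c) == 1) + (haps(l, c + 1) == 1);
    }
  }
  return M;
}

// Per-locus allele counts over a subset of individuals: (max_alleles x n_loci).
// [[Rcpp::export]]
IntegerMatrix cpp_allele_counts(RawMatrix haps, IntegerVector ind_idx,
                                int max_alleles) {
  int n_loci = haps.nrow();
  IntegerMatrix cnt(max_alleles, n_loci);
  for (int i = 0; i < ind_idx.size(); ++i) {
    for (int h = 0; h < 2; ++h) {
      const Rbyte *col = &haps(0, 2 * ind_idx[i] + h);
      for (int j = 0; j < n_loci; ++j) {
        int a = col[j];
        if (a < max_alleles) ++cnt(a, j);
      }
    }
  }
  return cnt;
}

// Sum of allelic effects over QTL for each individual (uncentred TBV).
// effects is (max_alleles x n_qtl); n_alleles bounds-checks allele codes.
// [[Rcpp::export]]
NumericVector cpp_tbv(RawMatrix haps, IntegerVector ind_idx,
                      IntegerVector qtl_idx, NumericMatrix effects,
                      IntegerVector n_alleles) {
  int n = ind_idx.size(), q = qtl_idx.size();
  NumericVector g(n);
  for (int i = 0; i < n; ++i) {
    int c = 2 * ind_idx[i];
    double s = 0;
    for (int j = 0; j < q; ++j) {
      int l = qtl_idx[j];
      int a0 = haps(l, c), a1 = haps(l, c + 1);
      if (a0 >= n_alleles[j] || a1 >= n_alleles[j])
        stop("unknown allele code at QTL %d", j + 1);
      s += effects(a0, j) + effects(a1, j);
    }
    g[i] = s;
  }
  return g;
}

// Inbreeding coefficients by the Meuwissen & Luo recursion.  sire/dam are
// 1-based with 0 = unknown; parents must precede offspring.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0);
  // F indexed 1..n with F[0] = -1 for the unknown parent convention.
  std::vector<double> Fv(n + 1, 0.0);
  Fv[0] = -1.0;
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s >= i || d >= i) stop("parents must precede offspring");
    if (s == 0 || d == 0) {
      Fv[i] = 0.0;
    } else {
      double fi = -1.0;
      std::set<int> anc;
      anc.insert(i);
      L[i] = 1.0;
      while (!anc.empty()) {
        int j = *anc.rbegin();
        anc.erase(std::prev(anc.end()));
        int sj = sire[j - 1], dj = dam[j - 1];
        double lj = L[j];
        if (sj > 0) { L[sj] += 0.5 * lj; anc.insert(sj); }
        if (dj > 0) { L[dj] += 0.5 * lj; anc.insert(dj); }
        double Dj = 0.5 - 0.25 * (Fv[sj] + Fv[dj]);
        fi += lj * lj * Dj;
        L[j] = 0.0;
      }
      Fv[i] = fi;
    }
    F[i - 1] = Fv[i];
  }
  return F;
}
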