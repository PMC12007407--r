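#include <Rcpp.h>
using namespace Rcpp;

// Tetraploid gene dropping down a topologically ordered pedigree.
//
// Each individual carries 4 allele labels. A gamete from parent p is,
// with probability alpha (double reduction), two copies of one
// uniformly chosen parental allele, otherwise two distinct uniformly
// chosen parental alleles. Unknown parents behave as unrelated
// non-inbred base individuals: their gametes use fresh labels (with the
// same double-reduction behaviour, which only matters through the
// duplicated-allele case).
//
// Returns an integer matrix nrep x (4*n); founder alleles of record i
// (0-based) are labelled 4*i+1 .. 4*i+4, fresh unknown-parent alleles
// get negative labels unique within a replicate.

static inline void gamete_known(const int *a, double alpha, int *g) {
  if (unif_rand() < alpha) {
    int k = (int)(unif_rand() * 4.0); if (k > 3) k = 3;
    g[0] = a[k]; g[1] = a[k];
  } else {
    int k = (int)(unif_rand() * 4.0); if (k > 3) k = 3;
    int l = (int)(unif_rand() * 3.0); if (l > 2) l = 2;
    if (l >= k) l++;
    g[0] = a[k]; g[1] = a[l];
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_gene_drop(IntegerVector p1, IntegerVector p2,
                            double alpha, int nrep) {
  const int n = p1.size();
  IntegerMatrix out(nrep, 4 * n);
  std::vector<int> g1(2), g2(2);
  for (int r = 0; r < nrep; ++r) {
    int fresh = 0;  // counter for unknown-parent labels (negative)
    int *row = new int[4 * n];
    for (int i = 0; i < n; ++i) {
      int s = p1[i], d = p2[i];  // 1-based, NA_INTEGER if unknown
      if (s == NA_INTEGER && d == NA_INTEGER) {
        for (int k = 0; k < 4; ++k) row[4 * i + k] = 4 * i + k + 1;
        continue;
      }
      if (s != NA_INTEGER) {
        gamete_known(row + 4 * (s - 1), alpha, g1.data());
      } else {
        if (unif_rand() < alpha) { --fresh; g1[0] = fresh; g1[1] = fresh; }
        else { g1[0] = --fresh; g1[1] = --fresh; }
      }
      if (d != NA_INTEGER) {
        gamete_known(row + 4 * (d - 1), alpha, g2.data());
      } else {
        if (unif_rand() < alpha) { --fresh; g2[0] = fresh; g2[1] = fresh; }
        else { g2[0] = --fresh; g2[1] = --fresh; }
      }
      row[4 * i] = g1[0]; row[4 * i + 1] = g1[1];
      row[4 * i + 2] = g2[0]; row[4 * i + 3] = g2[1];
    }
    for (int c = 0; c < 4 * n; ++c) out(r, c) = row[c];
    delete[] row;
  }
  return out;
}

// Monte-Carlo estimates of relationship-matrix entries from dropped
// genomes. For i != j the per-replicate kinship is the fraction of the
// 16 cross-individual allele pairs that match; A = 4 * mean. For i == j
// the per-replicate inbreeding is the fraction of the 6 within-
// individual pairs that match; A = 1 + 3 * mean. Returns estimate and
// its Monte-Carlo standard error per requested pair.
// [[Rcpp::export]]
NumericMatrix cpp_ibd_pairs(IntegerMatrix alleles, IntegerVector ia,
                            IntegerVector ja) {
  const int npair = ia.size(), nrep = alleles.nrow();
  NumericMatrix out(npair, 2);
  for (int p = 0; p < npair; ++p) {
    const int i = ia[p] - 1, j = ja[p] - 1;
    double sum = 0.0, sumsq = 0.0;
    if (i != j) {
      for (int r = 0; r < nrep; ++r) {
        int cnt = 0;
        for (int k = 0; k < 4; ++k)
          for (int l = 0; l < 4; ++l)
            if (alleles(r, 4 * i + k) == alleles(r, 4 * j + l)) ++cnt;
        double th = cnt / 16.0;
        sum += th; sumsq += th * th;
      }
      double m = sum / nrep;
      double v = (sumsq / nrep - m * m) * nrep / (nrep - 1.0);
      out(p, 0) = 4.0 * m;
      out(p, 1) = 4.0 * std::sqrt(v / nrep);
    } else {
      for (int r = 0; r < nrep; ++r) {
        int cnt = 0;
        for (int k = 0; k < 4; ++k)
          for (int l = k + 1; l < 4; ++l)
            if (alleles(r, 4 * i + k) == alleles(r, 4 * i + l)) ++cnt;
        double f = cnt / 6.0;
        sum += f; sumsq += f * f;
      }
      double m = sum / nrep;
      double v = (sumsq / nrep - m * m) * nrep / (nrep - 1.0);
      out(p, 0) = 1.0 + 3.0 * m;
      out(p, 1) = 3.0 * std::sqrt(v / nrep);
    }
  }
  return out;
}
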