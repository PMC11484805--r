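#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Tabular (recursive) numerator relationship matrix.  Pedigree must be
// topologically ordered; sire/dam are 1-based positions, 0 = unknown.
// [[Rcpp::export(name = ".tabular_A")]]
arma::mat tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree not topologically ordered (parent after offspring)");
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
    double asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm:
// F_i = sum_j L_ij^2 D_j - 1, accumulating the L row by walking up the
// ancestor list.  O(total ancestry depth), no dense matrix.
// [[Rcpp::export(name = ".inbreeding_ml")]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n, 0.0), D(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    double fs = (s >= 0) ? F[s] : -1.0;
    double fd = (d >= 0) ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (s < 0 && d < 0) { F[i] = 0.0; continue; }
    double fi = -1.0;
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      double lj = L[j];
      fi += lj * lj * D[j];
      int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * lj;
      if (dj >= 0) L[dj] += 0.5 * lj;
      L[j] = 0.0;
    }
    F[i] = fi;
  }
  return F;
}

// Gene dropping through an ordered pedigree.  founder_freq: per-marker
// allele frequency for founder haplotypes; returns dosage matrix (n x m).
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".gene_drop")]]
IntegerMatrix gene_drop(IntegerVector sire, IntegerVector dam,
                        NumericVector founder_freq) {
  int n = sire.size(), m = founder_freq.size();
  // haplotypes stored as bytes
  std::vector<unsigned char> h1((size_t)n * m), h2((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    unsigned char *H1 = &h1[(size_t)i * m], *H2 = &h2[(size_t)i * m];
    if (s < 0) {
      for (int j = 0; j < m; ++j)
        H1[j] = (unif_rand() < founder_freq[j]) ? 1 : 0;
    } else {
      const unsigned char *S1 = &h1[(size_t)s * m], *S2 = &h2[(size_t)s * m];
      for (int j = 0; j < m; ++j)
        H1[j] = (unif_rand() < 0.5) ? S1[j] : S2[j];
    }
    if (d < 0) {
      for (int j = 0; j < m; ++j)
        H2[j] = (unif_rand() < founder_freq[j]) ? 1 : 0;
    } else {
      const unsigned char *D1 = &h1[(size_t)d * m], *D2 = &h2[(size_t)d * m];
      for (int j = 0; j < m; ++j)
        H2[j] = (unif_rand() < 0.5) ? D1[j] : D2[j];
    }
  }
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = h1[(size_t)i * m + j] + h2[(size_t)i * m + j];
  return out;
}
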