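#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo recursion on the
// Cholesky decomposition A = L D L' of the numerator relationship matrix.
// `sire` and `dam` are 1-based indices into the topologically sorted
// pedigree (parents before offspring); 0 marks an unknown parent.
// For animal i, F_i = sum_j L_ij^2 d_j - 1, accumulated by walking the
// ancestor list of i with gene contributions halving at each step.
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n), v(n, 0.0);
  std::vector<int> touched;
  touched.reserve(256);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    if (s > i + 1 || dd > i + 1)
      stop("pedigree not sorted: parent listed after offspring");
    // Mendelian sampling variance scale for animal i
    if (s > 0 && dd > 0)
      d[i] = 0.5 - 0.25 * (F[s - 1] + F[dd - 1]);
    else if (s > 0)
      d[i] = 0.75 - 0.25 * F[s - 1];
    else if (dd > 0)
      d[i] = 0.75 - 0.25 * F[dd - 1];
    else
      d[i] = 1.0;

    if (s == 0 && dd == 0) { F[i] = 0.0; continue; }

    // accumulate L_i. over ancestors, descending index order
    touched.clear();
    v[i] = 1.0;
    touched.push_back(i);
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double vj = v[j];
      if (vj == 0.0) continue;
      aii += vj * vj * d[j];
      int sj = sire[j], dj = dam[j];
      if (sj > 0) { if (v[sj - 1] == 0.0) touched.push_back(sj - 1); v[sj - 1] += 0.5 * vj; }
      if (dj > 0) { if (v[dj - 1] == 0.0) touched.push_back(dj - 1); v[dj - 1] += 0.5 * vj; }
    }
    F[i] = aii - 1.0;
    for (size_t k = 0; k < touched.size(); ++k) v[touched[k]] = 0.0;
  }
  return F;
}
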