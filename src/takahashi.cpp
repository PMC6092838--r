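#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Takahashi selected inverse: given the lower-triangular Cholesky factor
// L (CSC arrays, rows sorted within columns) of a permuted symmetric
// positive-definite matrix P C P' = L L', compute the entries of the
// inverse (L L')^{-1} restricted to the sparsity pattern of L.
//
// Writing C = Lu D Lu' with unit-lower Lu (Lu_ij = L_ij / L_jj,
// d_j = L_jj^2), the inverse S satisfies, for i >= j,
//   S(j,j) = 1/d_j - sum_{k > j} Lu(k,j) S(k,j)
//   S(i,j) = -sum_{k > j} Lu(k,j) S(max(i,k), min(i,k)),  i > j,
// and every S entry referenced on the right lies inside the filled
// pattern (the column structures of a Cholesky factor are closed under
// the elimination tree), in columns already computed when j runs from
// n-1 down to 0.
//
// Returns the numeric values aligned with (Lp, Li).
// [[Rcpp::export(name = ".takahashi_selinv")]]
NumericVector takahashi_selinv(IntegerVector Lp, IntegerVector Li, NumericVector Lx, int n) {
  NumericVector S(Lx.size());
  std::vector<double> d(n);
  // unit-lower values reused in place of Lx
  std::vector<double> Lu(Lx.size());
  for (int j = 0; j < n; ++j) {
    int p0 = Lp[j], p1 = Lp[j + 1];
    if (p0 >= p1 || Li[p0] != j)
      stop("factor column %d lacks a diagonal entry", j + 1);
    double ljj = Lx[p0];
    d[j] = ljj * ljj;
    for (int p = p0; p < p1; ++p) Lu[p] = Lx[p] / ljj;
  }

  // lookup S(a,b) with a >= b by binary search in column b
  auto lookup = [&](int a, int b) -> double {
    const int *beg = &Li[0] + Lp[b], *end = &Li[0] + Lp[b + 1];
    const int *it = std::lower_bound(beg, end, a);
    if (it == end || *it != a) return 0.0; // outside pattern: structurally negligible
    return S[Lp[b] + (it - beg)];
  };

  for (int j = n - 1; j >= 0; --j) {
    int p0 = Lp[j], p1 = Lp[j + 1];
    // off-diagonals, any order within the column
    for (int p = p1 - 1; p > p0; --p) {
      int i = Li[p];
      double acc = 0.0;
      for (int q = p0 + 1; q < p1; ++q) {
        int k = Li[q];
        double skik = (k == i) ? lookup(i, i)
                    : (k < i) ? lookup(i, k) : lookup(k, i);
        acc += Lu[q] * skik;
      }
      S[p] = -acc;
    }
    double acc = 1.0 / d[j];
    for (int q = p0 + 1; q < p1; ++q) acc -= Lu[q] * S[q];
    S[p0] = acc;
  }
  return S;
}

// Vectorised lookup of entries of the symmetric selected inverse:
// queries (qi, qj) are 0-based indices in the permuted frame with
// qi >= qj; entries outside the stored pattern return 0.
// [[Rcpp::export(name = ".selinv_lookup")]]
NumericVector selinv_lookup(IntegerVector Lp, IntegerVector Li, NumericVector Sx,
                            IntegerVector qi, IntegerVector qj) {
  const int m = qi.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    int a = qi[t], b = qj[t];
    const int *beg = &Li[0] + Lp[b], *end = &Li[0] + Lp[b + 1];
    const int *it = std::lower_bound(beg, end, a);
    out[t] = (it != end && *it == a) ? Sx[Lp[b] + (it - beg)] : 0.0;
  }
  return out;
}
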