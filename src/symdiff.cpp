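#include <Rcpp.h>
using namespace Rcpp;

// Size of the symmetric difference of two sorted unique numeric vectors
// (encoded genome positions). Two-pointer merge, O(|a| + |b|).
static double symdiff_count(const NumericVector& av, const NumericVector& bv) {
  const double* a = REAL(av);
  const double* b = REAL(bv);
  R_xlen_t i = 0, j = 0, na = av.size(), nb = bv.size();
  R_xlen_t common = 0;
  while (i < na && j < nb) {
    // branchless advance: sorted-merge intersection count
    double x = a[i], y = b[j];
    common += (x == y);
    i += (x <= y);
    j += (y <= x);
  }
  return (double)na + (double)nb - 2.0 * (double)common;
}

// [[Rcpp::export(name = ".symdiff_count")]]
double symdiff_count_r(NumericVector a, NumericVector b) {
  return symdiff_count(a, b);
}

// Full pairwise symmetric-difference matrix over a list of sorted
// unique numeric vectors.
// [[Rcpp::export(name = ".symdiff_matrix")]]
NumericMatrix symdiff_matrix_r(List sets) {
  int n = sets.size();
  NumericMatrix m(n, n);
  std::vector<NumericVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<NumericVector>(sets[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = symdiff_count(v[i], v[j]);
      m(i, j) = d;
      m(j, i) = d;
    }
  }
  return m;
}
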