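#include <Rcpp.h>
using namespace Rcpp;

// Tabular method for the numerator relationship matrix A.
// sire/dam are 1-based positions in the (parents-before-offspring) ordering,
// 0 = unknown parent.
// [[Rcpp::export]]
NumericMatrix a_matrix_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree not ordered parents-before-offspring at individual %d", i + 1);
    double asd = (s > 0 && d > 0) ? A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s > 0) v += A(j, s - 1);
      if (d > 0) v += A(j, d - 1);
      v *= 0.5;
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}
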