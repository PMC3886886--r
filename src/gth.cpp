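#include <Rcpp.h>
using namespace Rcpp;

// Grassmann-Taksar-Heyman state reduction for the stationary distribution
// of an irreducible CTMC generator (dense, column-major). All operations
// are additions/multiplications of nonnegative numbers, so every component
// of pi is computed with full relative accuracy -- unlike LU solves, whose
// absolute error floor wipes out probabilities below ~1e-16 * max(pi).
// [[Rcpp::export(name = ".gth_stationary_cpp")]]
NumericVector gth_stationary_cpp(NumericMatrix Q) {
  const int n = Q.nrow();
  if (Q.ncol() != n) stop("Q must be square");
  NumericMatrix A(clone(Q));

  for (int k = n - 1; k >= 1; --k) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += A(k, j);
    if (s <= 0.0)
      stop("GTH reduction hit an absorbing block; the chain is reducible");
    for (int i = 0; i < k; ++i) A(i, k) /= s;
    for (int j = 0; j < k; ++j) {
      const double qkj = A(k, j);
      if (qkj != 0.0) {
        for (int i = 0; i < k; ++i) {
          if (i != j) A(i, j) += A(i, k) * qkj;
        }
      }
    }
  }

  NumericVector pi(n);
  pi[0] = 1.0;
  long double total = 1.0;
  for (int k = 1; k < n; ++k) {
    long double acc = 0.0;
    for (int i = 0; i < k; ++i) acc += (long double)pi[i] * A(i, k);
    pi[k] = (double)acc;
    total += acc;
  }
  for (int k = 0; k < n; ++k) pi[k] = (double)(pi[k] / total);
  return pi;
}
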