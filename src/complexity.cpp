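#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lempel-Ziv complexity counter c(N) of a symbol sequence under the
// exhaustive-history parsing rule (Kaspar & Schuster scheme): scan left to
// right, extending the current phrase while it can be copied from the
// already-seen history, and start a new phrase when it cannot.
// [[Rcpp::export]]
int lz76_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Approximate entropy phi^m(r) - phi^{m+1}(r) with self-matches included
// and Chebyshev (maximum) distance between embedding vectors. Plain O(N^2)
// double loop; this is the hot path of the complexity biomarkers.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) stop("sequence too short for ApEn with m=%d", m);
  double phi[2];
  for (int step = 0; step < 2; ++step) {
    int mm = m + step;
    int cnt = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < cnt; ++i) {
      int nm = 0;
      for (int j = 0; j < cnt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) { d = a; if (d > r) break; }
        }
        if (d <= r) ++nm;
      }
      acc += std::log((double)nm / cnt);
    }
    phi[step] = acc / cnt;
  }
  return phi[0] - phi[1];
}
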