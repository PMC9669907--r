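#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Categorical auto-recurrence statistics without materialising the n x n
// plot. Recurrence is exact code equality; the line of identity is excluded.
// Scans each diagonal offset d = 1..n-1 once (upper triangle; the plot is
// symmetric), accumulating recurrent-point and diagonal-line counts, so the
// whole computation is O(n^2) time and O(n) memory.
// [[Rcpp::export]]
List cpp_rqa(IntegerVector codes, int min_line) {
  int n = codes.size();
  long long rec_upper = 0, det_upper = 0;
  // maximal diagonal run lengths (upper triangle), indexed by length
  std::vector<long long> hist((size_t)n + 1, 0);
  const int *x = INTEGER(codes);

  for (int d = 1; d < n; ++d) {
    int run = 0;
    for (int i = 0; i + d < n; ++i) {
      if (x[i] == x[i + d]) {
        ++run;
      } else if (run > 0) {
        rec_upper += run;
        ++hist[run];
        if (run >= min_line) det_upper += run;
        run = 0;
      }
    }
    if (run > 0) {
      rec_upper += run;
      ++hist[run];
      if (run >= min_line) det_upper += run;
    }
  }

  long long n_recurrent = 2 * rec_upper; // both triangles
  double denom = (double)n * (n - 1);
  double pct_rec = denom > 0 ? 100.0 * n_recurrent / denom : 0.0;
  double pct_det =
      rec_upper > 0 ? 100.0 * (double)det_upper / (double)rec_upper : 0.0;

  int nnz = 0;
  for (int L = 1; L <= n; ++L)
    if (hist[L] > 0) ++nnz;
  IntegerVector lens(nnz);
  NumericVector counts(nnz);
  int k = 0;
  for (int L = 1; L <= n; ++L) {
    if (hist[L] > 0) {
      lens[k] = L;
      counts[k] = (double)hist[L];
      ++k;
    }
  }
  return List::create(_["n"] = n, _["n_recurrent"] = (double)n_recurrent,
                      _["pct_rec"] = pct_rec, _["pct_det"] = pct_det,
                      _["line_lengths"] = lens, _["line_counts"] = counts);
}
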