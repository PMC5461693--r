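#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global alignment score, linear gap penalty. O(len(a) * len(b)) cells,
// two-row rolling DP.
// [[Rcpp::export(name = ".nw_score")]]
double nw_score(std::string a, std::string b, double match, double mismatch,
                double gap) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = gap * (double)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = gap * (double)i;
    for (size_t j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
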