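#include <Rcpp.h>
#include <cctype>
#include <vector>

// Match-count global alignment: score 1 per identical aligned pair, 0 for
// mismatches and gaps. The optimum equals the longest-common-subsequence
// length, computed by the standard O(|a|*|b|) recurrence with a two-row
// table. Comparison is case-insensitive; only A/C/G/T can match ('N' and any
// other code matches nothing).

static inline char fold_base(char c) {
  char u = static_cast<char>(std::toupper(static_cast<unsigned char>(c)));
  switch (u) {
    case 'A': case 'C': case 'G': case 'T': return u;
    default: return 0;  // never matches, not even itself
  }
}

// [[Rcpp::export(name = ".lcs_match_count_cpp")]]
int lcs_match_count_cpp(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<char> fb(m);
  for (size_t j = 0; j < m; ++j) fb[j] = fold_base(b[j]);
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    const char ca = fold_base(a[i - 1]);
    for (size_t j = 1; j <= m; ++j) {
      if (ca != 0 && ca == fb[j - 1]) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
      }
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
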