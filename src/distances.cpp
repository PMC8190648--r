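#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <set>
using namespace Rcpp;

// Character-level Levenshtein with the classic two-row DP.
static int lev_dp(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static std::set<std::string> token_set(const std::string& s) {
  std::set<std::string> out;
  size_t i = 0;
  while (i < s.size()) {
    while (i < s.size() && s[i] == ' ') ++i;
    size_t j = i;
    while (j < s.size() && s[j] != ' ') ++j;
    if (j > i) out.insert(s.substr(i, j - i));
    i = j;
  }
  return out;
}

static double jaccard_dp(const std::string& a, const std::string& b) {
  std::set<std::string> ta = token_set(a), tb = token_set(b);
  if (ta.empty() && tb.empty()) return 0.0;
  size_t inter = 0;
  for (const auto& t : ta) if (tb.count(t)) ++inter;
  size_t uni = ta.size() + tb.size() - inter;
  return 1.0 - (double)inter / (double)uni;
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = lev_dp(sa, sb);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_jaccard(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = jaccard_dp(sa, sb);
  }
  return out;
}

// Inverse-distance similarity block: rows = candidate sentences, cols =
// catalog terms.  metric: 0 = levenshtein, 1 = jaccard, 2 = mean of the
// two inverse scores (not of the distances).
// [[Rcpp::export]]
NumericMatrix cpp_score_block(CharacterVector cands, CharacterVector terms, int metric) {
  R_xlen_t M = cands.size(), N = terms.size();
  std::vector<std::string> cs(M), ts(N);
  for (R_xlen_t i = 0; i < M; ++i) cs[i] = as<std::string>(cands[i]);
  for (R_xlen_t j = 0; j < N; ++j) ts[j] = as<std::string>(terms[j]);
  NumericMatrix out(M, N);
  for (R_xlen_t i = 0; i < M; ++i) {
    for (R_xlen_t j = 0; j < N; ++j) {
      double s;
      if (metric == 0) {
        s = 1.0 / (lev_dp(cs[i], ts[j]) + 1.0);
      } else if (metric == 1) {
        s = 1.0 / (jaccard_dp(cs[i], ts[j]) + 1.0);
      } else {
        double sl = 1.0 / (lev_dp(cs[i], ts[j]) + 1.0);
        double sj = 1.0 / (jaccard_dp(cs[i], ts[j]) + 1.0);
        s = 0.5 * (sl + sj);
      }
      out(i, j) = s;
    }
  }
  return out;
}
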