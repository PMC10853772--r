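#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'T': return 'A';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return 0;  // N etc. pair with nothing
  }
}

// Longest common substring length between each a[i] and b[i].
// Rolling single-row DP, O(|a|*|b|) time, O(|b|) space per pair.
// [[Rcpp::export(name = ".lcs_substring_len")]]
IntegerVector lcs_substring_len(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const std::string s = as<std::string>(a[k]);
    const std::string t = as<std::string>(b[k]);
    const size_t la = s.size(), lb = t.size();
    std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
    int best = 0;
    for (size_t i = 1; i <= la; ++i) {
      for (size_t j = 1; j <= lb; ++j) {
        if (s[i - 1] == t[j - 1]) {
          cur[j] = prev[j - 1] + 1;
          if (cur[j] > best) best = cur[j];
        } else {
          cur[j] = 0;
        }
      }
      std::swap(prev, cur);
    }
    out[k] = best;
  }
  return out;
}

// Longest fold-back stem: max run of pairings (i, j), (i+1, j-1), ... with
// s[i+t] complementary to s[j-t] and the two arms disjoint. Returns the arm
// (stem) length in nt for each sequence. No minimum loop size is imposed.
// [[Rcpp::export(name = ".foldback_len")]]
IntegerVector foldback_len(CharacterVector x) {
  const R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const std::string s = as<std::string>(x[k]);
    const int L = (int)s.size();
    int best = 0;
    if (L >= 2) {
      // R[i][j] = run length of pairings with outermost pair (i, j);
      // iterate by increasing j, keep previous column. R is sparse enough
      // to store as full (j - i) indexed vector per column.
      std::vector<int> prev(L, 0), cur(L, 0);  // indexed by i
      for (int j = 1; j < L; ++j) {
        for (int i = 0; i < j; ++i) {
          int run = 0;
          if (comp_base(s[j]) != 0 && s[i] == comp_base(s[j]))
            run = 1 + ((i + 1 <= j - 1 && j - 1 >= 1) ? prev[i + 1] : 0);
          cur[i] = run;
          if (run > 0) {
            int cap = (j - i + 1) / 2;  // arms must not cross
            int arm = run < cap ? run : cap;
            if (arm > best) best = arm;
          }
        }
        std::swap(prev, cur);
        std::fill(cur.begin(), cur.end(), 0);
      }
    }
    out[k] = best;
  }
  return out;
}
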