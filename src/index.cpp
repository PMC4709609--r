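// Text indexes over the sentinel-terminated DNA alphabet "$ACGNT".
// The sentinel '$' collates strictly below every residue (conveniently this
// is also ASCII order).  Suffix array by prefix doubling; BWT and a full
// per-position occurrence table back the FM-index used for backward search.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <string>
#include <vector>

using namespace Rcpp;

// '$' + 'A'..'Z', in ASCII (= collation) order.  DNA texts use the
// A/C/G/N/T subset; the general alphabet exists for the classic worked
// examples of these structures.
static const int SIGMA = 27;

int sym_code(char c) {
  if (c == '$') return 0;
  if (c >= 'A' && c <= 'Z') return c - 'A' + 1;
  return -1;
}

char sym_char(int c) { return c == 0 ? '$' : (char)('A' + c - 1); }

static void check_text(const std::string& t) {
  if (t.empty()) stop("text must be nonempty");
  for (size_t i = 0; i < t.size(); ++i) {
    if (sym_code(t[i]) < 0)
      stop("illegal symbol '%s' at position %d (alphabet is 'A'..'Z' + '$')",
           std::string(1, t[i]).c_str(), (int)(i + 1));
    if (t[i] == '$' && i + 1 != t.size())
      stop("sentinel '$' may only appear at the end of the text");
  }
  if (t.back() != '$') stop("text must be terminated by the '$' sentinel");
}

std::vector<int> suffix_array(const std::string& t) {
  const int n = (int)t.size();
  std::vector<int> sa(n), rank(n), tmp(n);
  for (int i = 0; i < n; ++i) {
    sa[i] = i;
    rank[i] = sym_code(t[i]);
  }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank[a] != rank[b]) return rank[a] < rank[b];
      int ra = a + k < n ? rank[a + k] : -1;
      int rb = b + k < n ? rank[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank = tmp;
    if (rank[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// [[Rcpp::export]]
IntegerVector build_suffix_array_cpp(std::string text) {
  check_text(text);
  std::vector<int> sa = suffix_array(text);
  return IntegerVector(sa.begin(), sa.end());
}

// [[Rcpp::export]]
List build_fm_cpp(std::string text) {
  check_text(text);
  const int n = (int)text.size();
  std::vector<int> sa = suffix_array(text);
  std::string bwt(n, ' ');
  for (int i = 0; i < n; ++i)
    bwt[i] = sa[i] == 0 ? text[n - 1] : text[sa[i] - 1];
  // counts[c] = number of symbols in the text strictly smaller than c
  IntegerVector counts(SIGMA);
  std::vector<int> freq(SIGMA, 0);
  for (char c : text) freq[sym_code(c)]++;
  int acc = 0;
  for (int c = 0; c < SIGMA; ++c) {
    counts[c] = acc;
    acc += freq[c];
  }
  {
    CharacterVector nm(SIGMA);
    for (int c = 0; c < SIGMA; ++c) nm[c] = std::string(1, sym_char(c));
    counts.names() = nm;
  }
  // occ(i, c) = occurrences of symbol c in bwt[0, i)
  IntegerMatrix occ(n + 1, SIGMA);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < SIGMA; ++c) occ(i + 1, c) = occ(i, c);
    occ(i + 1, sym_code(bwt[i]))++;
  }
  return List::create(_["n"] = n, _["sa"] = IntegerVector(sa.begin(), sa.end()),
                      _["bwt"] = bwt, _["counts"] = counts, _["occ"] = occ);
}

// backward extension lo/hi in C++ for tight loops (R wrapper exists too)
// [[Rcpp::export]]
IntegerVector backward_extend_cpp(IntegerVector counts, IntegerMatrix occ,
                                  int lo, int hi, std::string symbol) {
  if (symbol.size() != 1) stop("symbol must be a single character");
  int c = sym_code(symbol[0]);
  if (c < 0) stop("illegal symbol '%s'", symbol.c_str());
  int nlo = counts[c] + occ(lo, c);
  int nhi = counts[c] + occ(hi, c);
  return IntegerVector::create(nlo, nhi);
}

// LF-mapping walk from the sentinel row: reconstructs the text (invariant
// check used by tests and validate_fm_index()).
// [[Rcpp::export]]
std::string lf_reconstruct_cpp(std::string bwt, IntegerVector counts) {
  const int n = (int)bwt.size();
  std::vector<int> code(n), rank_at(n), seen(SIGMA, 0);
  for (int i = 0; i < n; ++i) {
    code[i] = sym_code(bwt[i]);
    if (code[i] < 0) stop("illegal symbol in bwt");
    rank_at[i] = seen[code[i]]++;
  }
  std::string out(n, ' ');
  int row = 0;  // row of the sentinel-starting rotation
  for (int k = n - 1; k >= 0; --k) {
    out[k] = bwt[row];
    row = counts[code[row]] + rank_at[row];
  }
  // the walk yields the rotation "$ t[0..n-2]"; rotate left by one for t
  return out.substr(1) + out[0];
}
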