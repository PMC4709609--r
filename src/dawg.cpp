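// Prefix DAWG of a query sequence: the minimal automaton over *prepend*
// transitions whose states are the equivalence classes of query substrings
// with identical suffix-array intervals (equivalently, identical start
// position sets).  Structurally this is the suffix automaton of the
// reversed query; transitions prepend a symbol on the left, so acceptance
// consumes a candidate string right-to-left.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

int sym_code(char c);   // from index.cpp; 0='$', 1..26 = 'A'..'Z'
char sym_char(int c);  // inverse

namespace {

static const int NSYM = 27;  // 0 = '$' (unused in queries), 1..26 = 'A'..'Z'

struct SamState {
  int len, link;
  int trans[NSYM];
  int pos;  // primary start position in the query, -1 for clones
  SamState(int l, int lk) : len(l), link(lk), pos(-1) {
    std::fill(trans, trans + NSYM, -1);
  }
};

struct Sam {
  std::vector<SamState> st;
  int last;
  Sam() {
    st.emplace_back(0, -1);
    last = 0;
  }
  void extend(int c, int endpos) {
    int cur = (int)st.size();
    st.emplace_back(st[last].len + 1, -1);
    st[cur].pos = endpos;
    int p = last;
    while (p != -1 && st[p].trans[c] == -1) {
      st[p].trans[c] = cur;
      p = st[p].link;
    }
    if (p == -1) {
      st[cur].link = 0;
    } else {
      int q = st[p].trans[c];
      if (st[p].len + 1 == st[q].len) {
        st[cur].link = q;
      } else {
        int clone = (int)st.size();
        st.push_back(st[q]);
        st[clone].len = st[p].len + 1;
        st[clone].pos = -1;
        while (p != -1 && st[p].trans[c] == q) {
          st[p].trans[c] = clone;
          p = st[p].link;
        }
        st[q].link = clone;
        st[cur].link = clone;
      }
    }
    last = cur;
  }
};

}  // namespace

// Builds the automaton for `query` (plain residues, no sentinel).
// Returns 0-based node ids; node 0 is the root.
// [[Rcpp::export]]
List build_dawg_cpp(std::string query) {
  const int n = (int)query.size();
  if (n == 0) stop("query must be nonempty");
  for (size_t i = 0; i < query.size(); ++i) {
    int c = sym_code(query[i]);
    if (c <= 0)
      stop("illegal symbol '%s' at position %d (alphabet is 'A'..'Z')",
           std::string(1, query[i]).c_str(), (int)(i + 1));
  }
  // suffix automaton of the reversed query; a primary state created while
  // consuming query[j] represents the suffix query[j..], whose start
  // position in the query is j.
  Sam sam;
  for (int j = n - 1; j >= 0; --j) sam.extend(sym_code(query[(size_t)j]), j);
  const int m = (int)sam.st.size();

  IntegerMatrix trans(m, 26);  // columns: 'A'..'Z' (symbol codes 1..26)
  IntegerVector len(m), link(m), primary_pos(m);
  for (int v = 0; v < m; ++v) {
    len[v] = sam.st[v].len;
    link[v] = sam.st[v].link;
    primary_pos[v] = sam.st[v].pos;
    for (int c = 1; c < NSYM; ++c) trans(v, c - 1) = sam.st[v].trans[c];
  }

  // reverse postorder over transitions from the root = topological order in
  // which every parent precedes every child.  Iterative DFS.
  std::vector<int> order;
  order.reserve(m);
  {
    std::vector<int> stack, nexti(m, 0);
    std::vector<char> seen(m, 0);
    stack.push_back(0);
    seen[0] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      bool descended = false;
      while (nexti[v] < 26) {
        int c = nexti[v]++;
        int w = trans(v, c);
        if (w >= 0 && !seen[w]) {
          seen[w] = 1;
          stack.push_back(w);
          descended = true;
          break;
        }
      }
      if (!descended && nexti[v] >= 26) {
        order.push_back(v);
        stack.pop_back();
      }
    }
    std::reverse(order.begin(), order.end());
  }

  // parent sets ar(a): nodes with a transition into a, with the edge symbol
  std::vector<std::vector<int>> par(m), parsym(m);
  for (int v = 0; v < m; ++v)
    for (int c = 0; c < 26; ++c) {
      int w = trans(v, c);
      if (w >= 0) {
        par[w].push_back(v);
        parsym[w].push_back(c + 1);  // symbol code
      }
    }
  List parents(m), parent_syms(m);
  for (int v = 0; v < m; ++v) {
    parents[v] = IntegerVector(par[v].begin(), par[v].end());
    parent_syms[v] = IntegerVector(parsym[v].begin(), parsym[v].end());
  }

  // suffix-link tree children, for on-demand position-set extraction
  std::vector<std::vector<int>> lc(m);
  for (int v = 1; v < m; ++v) lc[link[v]].push_back(v);
  List link_children(m);
  for (int v = 0; v < m; ++v)
    link_children[v] = IntegerVector(lc[v].begin(), lc[v].end());

  return List::create(_["n_nodes"] = m, _["query_len"] = n, _["len"] = len,
                      _["link"] = link, _["trans"] = trans,
                      _["order"] = IntegerVector(order.begin(), order.end()),
                      _["parents"] = parents,
                      _["parent_syms"] = parent_syms,
                      _["primary_pos"] = primary_pos,
                      _["link_children"] = link_children);
}

// start positions (in the query) of the substrings represented by `node`:
// primary positions of the node and of its suffix-link-tree descendants.
// [[Rcpp::export]]
IntegerVector dawg_positions_cpp(List dawg, int node) {
  List lc = dawg["link_children"];
  IntegerVector primary = dawg["primary_pos"];
  if (node < 0 || node >= (int)primary.size()) stop("node out of range");
  std::vector<int> out, stack{node};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (primary[v] >= 0) out.push_back(primary[v]);
    IntegerVector kids = lc[v];
    for (int k : kids) stack.push_back(k);
  }
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// does the automaton accept s (i.e. is s a substring of the query)?
// transitions prepend, so s is consumed right-to-left.
// [[Rcpp::export]]
bool dawg_accepts_cpp(List dawg, std::string s) {
  IntegerMatrix trans = dawg["trans"];
  int v = 0;
  for (int i = (int)s.size() - 1; i >= 0; --i) {
    int c = sym_code(s[(size_t)i]);
    if (c <= 0) return false;
    v = trans(v, c - 1);
    if (v < 0) return false;
  }
  return true;
}

// per-node suffix-array interval in the query's own FM-index: backward
// search of the node's longest represented substring.
// [[Rcpp::export]]
IntegerMatrix dawg_intervals_cpp(List dawg, IntegerVector counts,
                                 IntegerMatrix occ, std::string query) {
  IntegerVector len = dawg["len"], primary = dawg["primary_pos"];
  List lc = dawg["link_children"];
  const int m = len.size();
  const int n = (int)query.size();
  // find one start position per node (min primary in link subtree)
  std::vector<int> anypos(m, -1);
  // process nodes by decreasing len so children are resolved first
  std::vector<int> idx(m);
  for (int v = 0; v < m; ++v) idx[v] = v;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return len[a] > len[b]; });
  for (int v : idx) {
    int best = primary[v];
    IntegerVector kids = lc[v];
    for (int k : kids)
      if (anypos[k] >= 0 && (best < 0 || anypos[k] < best)) best = anypos[k];
    anypos[v] = best;
  }
  IntegerMatrix out(m, 2);
  for (int v = 0; v < m; ++v) {
    int lo = 0, hi = n + 1;  // full interval of the sentinel-terminated text
    if (v == 0) {
      out(v, 0) = lo;
      out(v, 1) = hi;
      continue;
    }
    int s = anypos[v], L = len[v];
    for (int i = s + L - 1; i >= s; --i) {
      int c = sym_code(query[(size_t)i]);
      int nlo = counts[c] + occ(lo, c);
      int nhi = counts[c] + occ(hi, c);
      lo = nlo;
      hi = nhi;
    }
    out(v, 0) = lo;
    out(v, 1) = hi;
  }
  return out;
}
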