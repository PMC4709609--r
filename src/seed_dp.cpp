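// Seeding dynamic programme over PrefixDawg(Q) x implicit prefix trie(R).
// States are (DAWG node a, reference suffix-array interval b) pairs holding
// the three affine scores: E (match state), F (gap along the query / DAWG
// direction) and K (gap along the reference / trie direction).  DAWG nodes
// are visited in reverse postorder (parents before children); trie nodes
// exist only as intervals and are expanded lazily by backward extension
// from retained states.  States whose best score E is not positive are
// discarded outright (the impossible value), which is what keeps the state
// set sparse.  Seed interval pairs are collected where E reaches the score
// threshold and the interval width is within the width threshold.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEGDP = INT_MIN / 4;

namespace {

struct St {
  int lo, hi;
  int Ediag, F, K, E;
  uint16_t qdE, rdE, qdF, rdF, qdK, rdK;
};

struct NodeStates {
  std::vector<St> v;
  std::unordered_map<uint64_t, int> idx;
  int get(int lo, int hi) {
    uint64_t key = ((uint64_t)(uint32_t)lo << 32) | (uint32_t)hi;
    auto it = idx.find(key);
    if (it != idx.end()) return it->second;
    St s;
    s.lo = lo;
    s.hi = hi;
    s.Ediag = s.F = s.K = s.E = NEGDP;
    s.qdE = s.rdE = s.qdF = s.rdF = s.qdK = s.rdK = 0;
    v.push_back(s);
    int i = (int)v.size() - 1;
    idx.emplace(key, i);
    return i;
  }
};

}  // namespace

// [[Rcpp::export]]
List bwasw_dp_cpp(List dawg, IntegerVector counts, IntegerMatrix occ,
                  int text_n, IntegerVector present, int match, int mismatch,
                  int gap_open, int gap_extend, bool special_n,
                  double max_interval_width, double min_seed_score,
                  double x_drop, bool collect_pairs) {
  IntegerMatrix trans = dawg["trans"];
  IntegerVector order = dawg["order"];
  List parents = dawg["parents"], parent_syms = dawg["parent_syms"];
  const int m = as<int>(dawg["n_nodes"]);

  std::vector<NodeStates> states(m);
  // root state: empty alignment, exempt from the positive-score rule
  {
    int i = states[0].get(0, text_n);
    states[0].v[i].E = 0;
  }

  auto bextend = [&](int lo, int hi, int c, int& nlo, int& nhi) {
    nlo = counts[c] + occ(lo, c);
    nhi = counts[c] + occ(hi, c);
  };

  int best_E = 0;
  std::vector<int> p_node, p_lo, p_hi, p_score, p_qd, p_rd;

  for (int oi = 0; oi < order.size(); ++oi) {
    int a = order[oi];
    NodeStates& S = states[a];

    // finalize E from diagonal and F contributions (precedence diag > F > K)
    for (auto& s : S.v) {
      if (s.E == 0 && a == 0) continue;  // root init state
      int E = NEGDP;
      uint16_t qd = 0, rd = 0;
      if (s.Ediag > E) { E = s.Ediag; qd = s.qdE; rd = s.rdE; }
      if (s.F > E) { E = s.F; qd = s.qdF; rd = s.rdF; }
      s.E = E;
      s.qdE = qd;
      s.rdE = rd;
    }

    // K-closure: gaps along the reference extend the interval within node a
    if (a != 0) {
      std::vector<int> work;
      work.reserve(S.v.size());
      for (int i = 0; i < (int)S.v.size(); ++i) work.push_back(i);
      while (!work.empty()) {
        int i = work.back();
        work.pop_back();
        // copy: S.v may reallocate on get()
        int sE = S.v[i].E, sK = S.v[i].K, slo = S.v[i].lo, shi = S.v[i].hi;
        uint16_t qdE = S.v[i].qdE, rdE = S.v[i].rdE, qdK = S.v[i].qdK,
                 rdK = S.v[i].rdK;
        int kc_open = sE == NEGDP ? NEGDP : sE - gap_open;
        int kc_ext = sK == NEGDP ? NEGDP : sK - gap_extend;
        int kcand = std::max(kc_open, kc_ext);
        if (kcand <= 0) continue;
        uint16_t qd = kc_open >= kc_ext ? qdE : qdK;
        uint16_t rd = kc_open >= kc_ext ? rdE : rdK;
        for (int pc = 0; pc < present.size(); ++pc) {
          int c = present[pc];
          int nlo, nhi;
          bextend(slo, shi, c, nlo, nhi);
          if (nhi <= nlo) continue;
          int j = S.get(nlo, nhi);
          St& t = S.v[j];
          if (kcand > t.K) {
            t.K = kcand;
            t.qdK = qd;
            t.rdK = (uint16_t)(rd + 1);
            if (kcand > t.E) {
              t.E = kcand;
              t.qdE = t.qdK;
              t.rdE = t.rdK;
            }
            work.push_back(j);
          }
        }
      }
      // drop impossible states (the positive-score rule), plus X-drop:
      // a state too far below a perfect match of its own query depth
      // cannot anchor a seed
      std::vector<St> kept;
      kept.reserve(S.v.size());
      for (auto& s : S.v)
        if (s.E > 0 && (double)s.qdE * match - s.E <= x_drop)
          kept.push_back(s);
      S.v.swap(kept);
      S.idx.clear();
      for (int i = 0; i < (int)S.v.size(); ++i)
        S.idx.emplace(((uint64_t)(uint32_t)S.v[i].lo << 32) |
                          (uint32_t)S.v[i].hi,
                      i);
    }

    // record best score and seed interval pairs
    for (auto& s : S.v) {
      if (a != 0 && s.E > best_E) best_E = s.E;
      if (collect_pairs && a != 0 && s.E >= min_seed_score &&
          (double)(s.hi - s.lo) <= max_interval_width) {
        p_node.push_back(a);
        p_lo.push_back(s.lo);
        p_hi.push_back(s.hi);
        p_score.push_back(s.E);
        p_qd.push_back(s.qdE);
        p_rd.push_back(s.rdE);
      }
    }

    // push to children: F consumes a query symbol only; the diagonal
    // consumes one query symbol (DAWG edge) and one reference symbol
    // (backward extension), scored by their pairwise substitution score.
    for (int c = 0; c < 26; ++c) {
      int child = trans(a, c);
      if (child < 0) continue;
      char qc = (char)('A' + c);
      NodeStates& T = states[child];
      for (int i = 0; i < (int)S.v.size(); ++i) {
        int sE = S.v[i].E, sF = S.v[i].F, slo = S.v[i].lo, shi = S.v[i].hi;
        uint16_t qdE = S.v[i].qdE, rdE = S.v[i].rdE, qdF = S.v[i].qdF,
                 rdF = S.v[i].rdF;
        // gap along the query (skip a reference move)
        int fo = sE == NEGDP ? NEGDP : sE - gap_open;
        int fe = sF == NEGDP ? NEGDP : sF - gap_extend;
        int fcand = std::max(fo, fe);
        if (fcand > 0) {
          int j = T.get(slo, shi);
          St& t = T.v[j];
          if (fcand > t.F) {
            t.F = fcand;
            t.qdF = (uint16_t)((fo >= fe ? qdE : qdF) + 1);
            t.rdF = fo >= fe ? rdE : rdF;
          }
        }
        // diagonal
        if (sE > NEGDP) {
          for (int pd = 0; pd < present.size(); ++pd) {
            int d = present[pd];
            int nlo, nhi;
            bextend(slo, shi, d, nlo, nhi);
            if (nhi <= nlo) continue;
            char rc = (char)('A' + d - 1);
            int sc = (qc == rc && !(special_n && qc == 'N')) ? match : mismatch;
            int ecand = sE + sc;
            if (ecand <= 0) continue;
            if ((double)(qdE + 1) * match - ecand > x_drop) continue;
            int j = T.get(nlo, nhi);
            St& t = T.v[j];
            if (ecand > t.Ediag) {
              t.Ediag = ecand;
              t.qdE = (uint16_t)(qdE + 1);
              t.rdE = (uint16_t)(rdE + 1);
            }
          }
        }
      }
      // free parent tables once all children received their pushes
    }
    // a's states are no longer needed once its children are pushed, except
    // that `a` itself may still be a child of a later node?  No: reverse
    // postorder guarantees all parents of every node come earlier, so once
    // we've pushed from `a` its table can be freed (pairs already copied).
    S.idx.clear();
    S.idx.rehash(0);
    std::vector<St>().swap(S.v);
  }

  List pairs = List::create(
      _["node"] = IntegerVector(p_node.begin(), p_node.end()),
      _["lo"] = IntegerVector(p_lo.begin(), p_lo.end()),
      _["hi"] = IntegerVector(p_hi.begin(), p_hi.end()),
      _["score"] = IntegerVector(p_score.begin(), p_score.end()),
      _["q_len"] = IntegerVector(p_qd.begin(), p_qd.end()),
      _["r_len"] = IntegerVector(p_rd.begin(), p_rd.end()));
  return List::create(_["best_score"] = best_E, _["pairs"] = pairs);
}

// expand seed interval pairs into concrete seeds via the suffix array and
// the DAWG start-position sets; deduplicate on (q_pos, r_pos) keeping the
// best-scoring (then longest) seed.
// [[Rcpp::export]]
List seeds_from_pairs_cpp(IntegerVector node, IntegerVector lo,
                          IntegerVector hi, IntegerVector score,
                          IntegerVector q_len, IntegerVector r_len,
                          IntegerVector sa, List dawg) {
  List lc = dawg["link_children"];
  IntegerVector primary = dawg["primary_pos"];
  std::unordered_map<uint64_t, int> best;  // (q_pos, r_pos) -> seed index
  std::vector<int> q_pos, r_pos, slen_q, slen_r, sscore;
  std::vector<int> positions, stack;
  for (int p = 0; p < node.size(); ++p) {
    positions.clear();
    stack.clear();
    stack.push_back(node[p]);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (primary[v] >= 0) positions.push_back(primary[v]);
      IntegerVector kids = lc[v];
      for (int k : kids) stack.push_back(k);
    }
    std::sort(positions.begin(), positions.end());
    for (int i = lo[p]; i < hi[p]; ++i) {
      int rp = sa[i];
      for (int qp : positions) {
        uint64_t key = ((uint64_t)(uint32_t)qp << 32) | (uint32_t)rp;
        auto it = best.find(key);
        if (it == best.end()) {
          q_pos.push_back(qp);
          r_pos.push_back(rp);
          slen_q.push_back(q_len[p]);
          slen_r.push_back(r_len[p]);
          sscore.push_back(score[p]);
          best.emplace(key, (int)q_pos.size() - 1);
        } else {
          int j = it->second;
          if (score[p] > sscore[j] ||
              (score[p] == sscore[j] && q_len[p] > slen_q[j])) {
            slen_q[j] = q_len[p];
            slen_r[j] = r_len[p];
            sscore[j] = score[p];
          }
        }
      }
    }
  }
  // deterministic order: by (q_pos, r_pos)
  std::vector<int> ord(q_pos.size());
  for (int i = 0; i < (int)ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (q_pos[x] != q_pos[y]) return q_pos[x] < q_pos[y];
    return r_pos[x] < r_pos[y];
  });
  auto pick = [&](const std::vector<int>& v) {
    IntegerVector out(ord.size());
    for (int i = 0; i < (int)ord.size(); ++i) out[i] = v[ord[i]];
    return out;
  };
  return List::create(_["q_pos"] = pick(q_pos), _["r_pos"] = pick(r_pos),
                      _["q_len"] = pick(slen_q), _["r_len"] = pick(slen_r),
                      _["score"] = pick(sscore));
}
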