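// Dynamic programming for parsimony on linearly ordered (Wagner) multistate
// characters with unit step cost |i - j|, plus an unordered (Fitch-like) mode.
// The min-plus convolution with the |i - j| cost is a 1-D distance transform,
// so each edge costs O(S) per character instead of O(S^2).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const int BIG = std::numeric_limits<int>::max() / 4;

// in place: f[s] <- min_j f[j] + |j - s|
static inline void dt_ordered(int *f, int S) {
  for (int s = 1; s < S; ++s)
    if (f[s - 1] + 1 < f[s]) f[s] = f[s - 1] + 1;
  for (int s = S - 2; s >= 0; --s)
    if (f[s + 1] + 1 < f[s]) f[s] = f[s + 1] + 1;
}

// in place: f[s] <- min(f[s], min_j f[j] + 1)   (unordered unit cost)
static inline void dt_unordered(int *f, int S) {
  int m = BIG;
  for (int s = 0; s < S; ++s) m = std::min(m, f[s]);
  for (int s = 0; s < S; ++s) if (m + 1 < f[s]) f[s] = m + 1;
}

struct Topo {
  int ntot, root;
  std::vector<std::vector<int> > kids;   // 1-based node ids
  std::vector<int> preorder;             // parents before children
  std::vector<int> parent_edge;          // node -> row of edge matrix (0-based), -1 for root
};

static Topo build_topo(const IntegerMatrix &edge, int ntip) {
  int ne = edge.nrow();
  int ntot = ntip;
  for (int i = 0; i < ne; ++i) {
    ntot = std::max(ntot, edge(i, 0));
    ntot = std::max(ntot, edge(i, 1));
  }
  Topo t;
  t.ntot = ntot;
  t.kids.assign(ntot + 1, std::vector<int>());
  t.parent_edge.assign(ntot + 1, -1);
  std::vector<char> is_child(ntot + 1, 0);
  for (int i = 0; i < ne; ++i) {
    t.kids[edge(i, 0)].push_back(edge(i, 1));
    is_child[edge(i, 1)] = 1;
    t.parent_edge[edge(i, 1)] = i;
  }
  t.root = -1;
  for (int v = ntip + 1; v <= ntot; ++v)
    if (!is_child[v] && !t.kids[v].empty()) { t.root = v; break; }
  if (t.root < 0) stop("could not locate a root node in the edge matrix");
  std::vector<int> stack;
  stack.push_back(t.root);
  t.preorder.reserve(ntot);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    t.preorder.push_back(v);
    for (size_t j = 0; j < t.kids[v].size(); ++j) stack.push_back(t.kids[v][j]);
  }
  return t;
}

// Fill leaf cost rows and run the down (post-order) pass.
// D is (ntot+1) x (C*S), D[v][c*S+s] = min cost of subtree(v) given state s at v.
static void down_pass(const Topo &t, const IntegerMatrix &states, int S,
                      bool ordered, std::vector<std::vector<int> > &D) {
  int ntip = states.nrow(), C = states.ncol();
  D.assign(t.ntot + 1, std::vector<int>());
  for (int v = 1; v <= ntip; ++v) {
    D[v].assign(C * S, BIG);
    for (int c = 0; c < C; ++c) {
      int st = states(v - 1, c);
      if (st == NA_INTEGER || st < 0 || st >= S)
        stop("leaf state out of range or missing");
      D[v][c * S + st] = 0;
    }
  }
  std::vector<int> tmp(S);
  for (int i = (int)t.preorder.size() - 1; i >= 0; --i) {
    int v = t.preorder[i];
    if (t.kids[v].empty()) continue;
    D[v].assign(C * S, 0);
    for (size_t j = 0; j < t.kids[v].size(); ++j) {
      int ch = t.kids[v][j];
      for (int c = 0; c < C; ++c) {
        std::copy(D[ch].begin() + c * S, D[ch].begin() + (c + 1) * S, tmp.begin());
        if (ordered) dt_ordered(&tmp[0], S); else dt_unordered(&tmp[0], S);
        int *dv = &D[v][c * S];
        for (int s = 0; s < S; ++s) dv[s] += tmp[s];
      }
    }
  }
}

// Per-character minimal length of the tree; if anc has length C the hypothetical
// ancestor (fixed states) is attached at the root and its edge cost is included.
// [[Rcpp::export]]
IntegerVector tree_length_ordered_cpp(IntegerMatrix edge, int ntip,
                                      IntegerMatrix states, int n_states,
                                      IntegerVector anc, bool ordered) {
  Topo t = build_topo(edge, ntip);
  int C = states.ncol(), S = n_states;
  std::vector<std::vector<int> > D;
  down_pass(t, states, S, ordered, D);
  bool has_anc = anc.size() == C;
  if (anc.size() != 0 && !has_anc) stop("anc must be empty or one state per character");
  IntegerVector out(C);
  for (int c = 0; c < C; ++c) {
    int best = BIG;
    const int *dr = &D[t.root][c * S];
    for (int s = 0; s < S; ++s) {
      int val = dr[s];
      if (has_anc) val += ordered ? std::abs(s - anc[c]) : (s == anc[c] ? 0 : 1);
      if (val < best) best = val;
    }
    out[c] = best;
  }
  return out;
}

// Lundberg rooting: total rooted length obtained by attaching a hypothetical
// ancestor (fixed states anc) in the middle of each edge of the (unrooted,
// arbitrarily oriented) tree. Returns one total length per edge row.
// [[Rcpp::export]]
NumericVector lundberg_edge_lengths_cpp(IntegerMatrix edge, int ntip,
                                        IntegerMatrix states, int n_states,
                                        IntegerVector anc, bool ordered) {
  Topo t = build_topo(edge, ntip);
  int C = states.ncol(), S = n_states, ne = edge.nrow();
  if (anc.size() != C) stop("anc must hold one ancestral state per character");
  std::vector<std::vector<int> > D;
  down_pass(t, states, S, ordered, D);

  // DTD[child] = distance-transformed D of the child (cost seen from parent side)
  std::vector<std::vector<int> > DTD(t.ntot + 1), U(t.ntot + 1);
  std::vector<int> tmp(S);
  for (int v = 1; v <= t.ntot; ++v) {
    if (v == t.root) continue;
    DTD[v].assign(C * S, 0);
    for (int c = 0; c < C; ++c) {
      std::copy(D[v].begin() + c * S, D[v].begin() + (c + 1) * S, tmp.begin());
      if (ordered) dt_ordered(&tmp[0], S); else dt_unordered(&tmp[0], S);
      std::copy(tmp.begin(), tmp.end(), DTD[v].begin() + c * S);
    }
  }
  // up pass: U[v][c*S+s] = min cost of tree minus subtree(v), given state s at v
  // (for v = root the complement is empty)
  U[t.root].assign(C * S, 0);
  for (size_t i = 0; i < t.preorder.size(); ++i) {
    int v = t.preorder[i];
    if (t.kids[v].empty()) continue;
    std::vector<int> tot(C * S);
    for (int c = 0; c < C; ++c) {
      int *tv = &tot[c * S];
      const int *uv = &U[v][c * S];
      for (int s = 0; s < S; ++s) tv[s] = uv[s];
      for (size_t j = 0; j < t.kids[v].size(); ++j) {
        const int *dd = &DTD[t.kids[v][j]][c * S];
        for (int s = 0; s < S; ++s) tv[s] += dd[s];
      }
    }
    for (size_t j = 0; j < t.kids[v].size(); ++j) {
      int ch = t.kids[v][j];
      U[ch].assign(C * S, 0);
      for (int c = 0; c < C; ++c) {
        const int *tv = &tot[c * S];
        const int *dd = &DTD[ch][c * S];
        for (int s = 0; s < S; ++s) tmp[s] = tv[s] - dd[s];
        if (ordered) dt_ordered(&tmp[0], S); else dt_unordered(&tmp[0], S);
        std::copy(tmp.begin(), tmp.end(), U[ch].begin() + c * S);
      }
    }
  }
  NumericVector out(ne);
  for (int i = 0; i < ne; ++i) {
    int ch = edge(i, 1);
    double tot = 0.0;
    for (int c = 0; c < C; ++c) {
      int best = BIG;
      const int *dd = &DTD[ch][c * S];
      const int *uu = &U[ch][c * S];
      for (int s = 0; s < S; ++s) {
        int cost = dd[s] + uu[s] +
          (ordered ? std::abs(s - anc[c]) : (s == anc[c] ? 0 : 1));
        if (cost < best) best = cost;
      }
      tot += best;
    }
    out[i] = tot;
  }
  return out;
}

// Batch scoring: total lengths of many topologies sharing one leaf set.
// [[Rcpp::export]]
NumericVector tree_lengths_many_cpp(List edges, int ntip,
                                    IntegerMatrix states, int n_states,
                                    IntegerVector anc, bool ordered) {
  int m = edges.size(), C = states.ncol(), S = n_states;
  bool has_anc = anc.size() == C;
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    IntegerMatrix edge = edges[t];
    Topo tp = build_topo(edge, ntip);
    std::vector<std::vector<int> > D;
    down_pass(tp, states, S, ordered, D);
    double tot = 0.0;
    for (int c = 0; c < C; ++c) {
      int best = BIG;
      const int *dr = &D[tp.root][c * S];
      for (int s = 0; s < S; ++s) {
        int val = dr[s];
        if (has_anc) val += ordered ? std::abs(s - anc[c]) : (s == anc[c] ? 0 : 1);
        if (val < best) best = val;
      }
      tot += best;
    }
    out[t] = tot;
  }
  return out;
}

// MPR state intervals on a rooted tree, optionally with a hypothetical ancestor
// of fixed states attached above the root. Returns lo and hi matrices
// ((ntip + Nnode) x C, 0-based states) and the per-character minimal length.
// [[Rcpp::export]]
List mpr_intervals_cpp(IntegerMatrix edge, int ntip,
                       IntegerMatrix states, int n_states,
                       IntegerVector anc) {
  Topo t = build_topo(edge, ntip);
  int C = states.ncol(), S = n_states;
  bool has_anc = anc.size() == C;
  if (anc.size() != 0 && !has_anc) stop("anc must be empty or one state per character");
  std::vector<std::vector<int> > D;
  down_pass(t, states, S, true, D);

  std::vector<std::vector<int> > DTD(t.ntot + 1), U(t.ntot + 1);
  std::vector<int> tmp(S);
  for (int v = 1; v <= t.ntot; ++v) {
    if (v == t.root) continue;
    DTD[v].assign(C * S, 0);
    for (int c = 0; c < C; ++c) {
      std::copy(D[v].begin() + c * S, D[v].begin() + (c + 1) * S, tmp.begin());
      dt_ordered(&tmp[0], S);
      std::copy(tmp.begin(), tmp.end(), DTD[v].begin() + c * S);
    }
  }
  U[t.root].assign(C * S, 0);
  if (has_anc)
    for (int c = 0; c < C; ++c)
      for (int s = 0; s < S; ++s) U[t.root][c * S + s] = std::abs(s - anc[c]);
  for (size_t i = 0; i < t.preorder.size(); ++i) {
    int v = t.preorder[i];
    if (t.kids[v].empty()) continue;
    std::vector<int> tot(C * S);
    for (int c = 0; c < C; ++c) {
      int *tv = &tot[c * S];
      const int *uv = &U[v][c * S];
      for (int s = 0; s < S; ++s) tv[s] = uv[s];
      for (size_t j = 0; j < t.kids[v].size(); ++j) {
        const int *dd = &DTD[t.kids[v][j]][c * S];
        for (int s = 0; s < S; ++s) tv[s] += dd[s];
      }
    }
    for (size_t j = 0; j < t.kids[v].size(); ++j) {
      int ch = t.kids[v][j];
      U[ch].assign(C * S, 0);
      for (int c = 0; c < C; ++c) {
        const int *tv = &tot[c * S];
        const int *dd = &DTD[ch][c * S];
        for (int s = 0; s < S; ++s) tmp[s] = tv[s] - dd[s];
        dt_ordered(&tmp[0], S);
        std::copy(tmp.begin(), tmp.end(), U[ch].begin() + c * S);
      }
    }
  }
  IntegerVector len(C);
  IntegerMatrix lo(t.ntot, C), hi(t.ntot, C);
  for (int c = 0; c < C; ++c) {
    int best = BIG;
    for (int s = 0; s < S; ++s) {
      int val = D[t.root][c * S + s] + U[t.root][c * S + s];
      if (val < best) best = val;
    }
    len[c] = best;
    for (int v = 1; v <= t.ntot; ++v) {
      int l = -1, h = -1;
      const std::vector<int> &dv = D[v];
      const std::vector<int> &uv = U[v];
      for (int s = 0; s < S; ++s) {
        if (dv[c * S + s] >= BIG) continue;
        int val = dv[c * S + s] + uv[c * S + s];
        if (val == best) { if (l < 0) l = s; h = s; }
      }
      lo(v - 1, c) = l;
      hi(v - 1, c) = h;
    }
  }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["length"] = len,
                      _["root"] = t.root);
}
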