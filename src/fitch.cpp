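#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Small-parsimony machinery. Character states are bitmasks over {A,C,G,T}
// (A=1, C=2, G=4, T=8); missing data (N, gap) is the full wildcard 15.
// Internal nodes are scored by the counting form of the Fitch downpass
// (Hartigan): a node's state set is the set of bases contained in the
// maximal number of child sets, and the node contributes
// (#children - max count) changes. For binary nodes this is exactly the
// Fitch intersection/union rule.

struct TreeIdx {
  int n_nodes, n_tips, root;
  std::vector<int> parent;                 // 0 for root, 1-based otherwise
  std::vector<std::vector<int> > children; // per node
  std::vector<int> postorder;              // node indices, tips included
};

static TreeIdx build_tree(const IntegerMatrix& edge, int n_tips) {
  TreeIdx t;
  int n_nodes = 0;
  for (int k = 0; k < edge.nrow(); ++k)
    n_nodes = std::max(n_nodes, std::max(edge(k, 0), edge(k, 1)));
  t.n_nodes = n_nodes;
  t.n_tips = n_tips;
  t.parent.assign(n_nodes + 1, 0);
  t.children.assign(n_nodes + 1, std::vector<int>());
  for (int k = 0; k < edge.nrow(); ++k) {
    int p = edge(k, 0), c = edge(k, 1);
    t.parent[c] = p;
    t.children[p].push_back(c);
  }
  t.root = n_tips + 1; // ape convention
  // iterative postorder
  t.postorder.reserve(n_nodes);
  std::vector<int> stack1, stack2;
  stack1.push_back(t.root);
  while (!stack1.empty()) {
    int u = stack1.back(); stack1.pop_back();
    stack2.push_back(u);
    for (size_t i = 0; i < t.children[u].size(); ++i)
      stack1.push_back(t.children[u][i]);
  }
  for (int i = (int)stack2.size() - 1; i >= 0; --i)
    t.postorder.push_back(stack2[i]);
  return t;
}

// Combine child sets at a node: given bitmask sets, return the node set and
// add the local change count to *cost.
static inline int combine_sets(const std::vector<int>& sets, int* cost) {
  int cnt[4] = {0, 0, 0, 0};
  for (size_t i = 0; i < sets.size(); ++i) {
    int s = sets[i];
    if (s & 1) ++cnt[0];
    if (s & 2) ++cnt[1];
    if (s & 4) ++cnt[2];
    if (s & 8) ++cnt[3];
  }
  int k = std::max(std::max(cnt[0], cnt[1]), std::max(cnt[2], cnt[3]));
  int set = 0;
  if (cnt[0] == k) set |= 1;
  if (cnt[1] == k) set |= 2;
  if (cnt[2] == k) set |= 4;
  if (cnt[3] == k) set |= 8;
  *cost += (int)sets.size() - k;
  return set;
}

// Total parsimony score of a tree. tip_states: n_tips x n_cols bitmask
// matrix, row r = tip with index r+1 in the edge matrix.
// [[Rcpp::export(name = ".fitch_total_cpp")]]
int fitch_total_cpp(IntegerMatrix edge, int n_tips, IntegerMatrix tip_states) {
  TreeIdx t = build_tree(edge, n_tips);
  int ncol = tip_states.ncol();
  int total = 0;
  std::vector<int> D((t.n_nodes + 1));
  std::vector<int> sets;
  for (int col = 0; col < ncol; ++col) {
    for (size_t idx = 0; idx < t.postorder.size(); ++idx) {
      int u = t.postorder[idx];
      if (u <= n_tips) { D[u] = tip_states(u - 1, col); continue; }
      sets.clear();
      for (size_t i = 0; i < t.children[u].size(); ++i)
        sets.push_back(D[t.children[u][i]]);
      D[u] = combine_sets(sets, &total);
    }
  }
  return total;
}

// Per-edge attachment scores for each query: column 0 is the root
// attachment, column e (1-based) is edge row e of the edge matrix. Used for
// oracle-equivalence checks and shares the incremental path-rescoring logic
// with the placement driver below.
// [[Rcpp::export(name = ".attachment_scores_cpp")]]
IntegerMatrix attachment_scores_cpp(IntegerMatrix edge, int n_tips,
                                    IntegerMatrix tip_states,
                                    IntegerMatrix query_states) {
  TreeIdx t = build_tree(edge, n_tips);
  int ncol = tip_states.ncol();
  int nE = edge.nrow();
  int nq = query_states.nrow();
  std::vector<std::vector<int> > D(t.n_nodes + 1, std::vector<int>(ncol));
  std::vector<std::vector<int> > L(t.n_nodes + 1, std::vector<int>(ncol, 0));
  int base_score = 0;
  {
    std::vector<int> sets;
    for (int col = 0; col < ncol; ++col) {
      for (size_t idx = 0; idx < t.postorder.size(); ++idx) {
        int u = t.postorder[idx];
        if (u <= n_tips) { D[u][col] = tip_states(u - 1, col); continue; }
        sets.clear();
        for (size_t i = 0; i < t.children[u].size(); ++i)
          sets.push_back(D[t.children[u][i]][col]);
        int cost = 0;
        D[u][col] = combine_sets(sets, &cost);
        L[u][col] = cost;
        base_score += cost;
      }
    }
  }
  IntegerMatrix out(nq, nE + 1);
  std::vector<int> sets;
  for (int qi = 0; qi < nq; ++qi) {
    long sc0 = base_score;
    for (int col = 0; col < ncol; ++col) {
      if ((D[t.root][col] & query_states(qi, col)) == 0) ++sc0;
    }
    out(qi, 0) = (int)sc0;
    for (int e = 0; e < nE; ++e) {
      int p = edge(e, 0), c = edge(e, 1);
      long sc = base_score;
      for (int col = 0; col < ncol; ++col) {
        int q = query_states(qi, col);
        int inter = D[c][col] & q;
        int vset;
        if (inter) vset = inter;
        else { vset = D[c][col] | q; ++sc; }
        int child = c, u = p, carry = vset;
        while (u != 0) {
          sets.clear();
          for (size_t i = 0; i < t.children[u].size(); ++i) {
            int ch = t.children[u][i];
            sets.push_back(ch == child ? carry : D[ch][col]);
          }
          int cost = 0;
          int uset = combine_sets(sets, &cost);
          sc += cost - L[u][col];
          if (uset == D[u][col] && cost == L[u][col]) break;
          carry = uset; child = u; u = t.parent[u];
        }
      }
      out(qi, e + 1) = (int)sc;
    }
  }
  return out;
}

// Evaluate the parsimony score of attaching each query as a new tip on every
// edge of the tree (plus attachment at the root, reported as edge 0). For
// edge e = (p, c) the query joins a new node subdividing e; only the path
// from c to the root needs rescoring, which is done per column with early
// exit when the updated state set and local cost match the stored ones.
//
// edge_depth: per edge-row depth used for tie-breaking (root-most wins),
// with the root attachment assigned depth -1 implicitly.
// Returns, per query: best_edge (0 = root), score, second-best score,
// tie count at the best score.
// [[Rcpp::export(name = ".place_queries_cpp")]]
List place_queries_cpp(IntegerMatrix edge, int n_tips, IntegerMatrix tip_states,
                       IntegerMatrix query_states, IntegerVector edge_depth) {
  TreeIdx t = build_tree(edge, n_tips);
  int ncol = tip_states.ncol();
  int nE = edge.nrow();
  int nq = query_states.nrow();

  // Base down-sets and per-node local costs, per column.
  std::vector<std::vector<int> > D(t.n_nodes + 1, std::vector<int>(ncol));
  std::vector<std::vector<int> > L(t.n_nodes + 1, std::vector<int>(ncol, 0));
  int base_score = 0;
  {
    std::vector<int> sets;
    for (int col = 0; col < ncol; ++col) {
      for (size_t idx = 0; idx < t.postorder.size(); ++idx) {
        int u = t.postorder[idx];
        if (u <= n_tips) { D[u][col] = tip_states(u - 1, col); continue; }
        sets.clear();
        for (size_t i = 0; i < t.children[u].size(); ++i)
          sets.push_back(D[t.children[u][i]][col]);
        int cost = 0;
        D[u][col] = combine_sets(sets, &cost);
        L[u][col] = cost;
        base_score += cost;
      }
    }
  }

  IntegerVector out_edge(nq), out_score(nq), out_second(nq), out_ties(nq);
  std::vector<int> sets;

  for (int qi = 0; qi < nq; ++qi) {
    // candidate 0: attach at the root (new root, children = {old root, query})
    long best = -1, second = -1;
    int best_edge = 0, best_depth = -1, ties = 0;
    {
      long sc = base_score;
      for (int col = 0; col < ncol; ++col) {
        int q = query_states(qi, col);
        if ((D[t.root][col] & q) == 0) ++sc;
      }
      best = sc; second = -1; best_edge = 0; best_depth = -1; ties = 1;
    }
    for (int e = 0; e < nE; ++e) {
      int p = edge(e, 0), c = edge(e, 1);
      long sc = base_score;
      for (int col = 0; col < ncol; ++col) {
        int q = query_states(qi, col);
        // new node v subdividing (p, c), children {c, query}
        int inter = D[c][col] & q;
        int vset;
        if (inter) vset = inter;
        else { vset = D[c][col] | q; ++sc; }
        // walk up from p, child c's slot now carries vset
        int child = c, u = p, carry = vset;
        while (u != 0) {
          sets.clear();
          for (size_t i = 0; i < t.children[u].size(); ++i) {
            int ch = t.children[u][i];
            sets.push_back(ch == child ? carry : D[ch][col]);
          }
          int cost = 0;
          int uset = combine_sets(sets, &cost);
          sc += cost - L[u][col];
          if (uset == D[u][col] && cost == L[u][col]) break; // ancestors unchanged
          carry = uset; child = u; u = t.parent[u];
        }
      }
      int dep = edge_depth[e];
      if (sc < best) {
        second = best; best = sc; best_edge = e + 1; best_depth = dep; ties = 1;
      } else if (sc == best) {
        ++ties;
        if (dep < best_depth) { best_edge = e + 1; best_depth = dep; }
        // equal depth: keep earlier (smaller) edge id
        if (second < 0 || sc < second) { /* second stays the tied best */ }
        second = (second < 0) ? sc : std::min(second, sc);
      } else if (second < 0 || sc < second) {
        second = sc;
      }
    }
    out_edge[qi] = best_edge;
    out_score[qi] = (int)best;
    out_second[qi] = (int)(second < 0 ? best : second);
    out_ties[qi] = ties;
  }
  return List::create(_["best_edge"] = out_edge, _["score"] = out_score,
                      _["second"] = out_second, _["tie_count"] = out_ties);
}
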