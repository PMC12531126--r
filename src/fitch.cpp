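// Fitch small-parsimony scoring and exact maximum-parsimony search over
// binary event characters. Character states are encoded as bitmasks:
// 1 = state 0, 2 = state 1, 3 = ambiguous {0,1}.

#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Fitch score of a rooted (possibly multifurcating) tree given a parent
// vector (1-based, 0 for the root). leafMask is nNodes x nChar; an all-zero
// row marks a pure internal node. A node may carry both a mask and
// children (an ancestral subclone observed as an internal node): its own
// mask is folded in like an extra child.
// [[Rcpp::export]]
int cpp_fitch_parent(IntegerVector parent, IntegerMatrix leafMask) {
  const int n = parent.size();
  const int nChar = leafMask.ncol();
  std::vector<std::vector<int>> kids(n);
  int root = -1;
  for (int i = 0; i < n; ++i) {
    if (parent[i] == 0) root = i;
    else kids[parent[i] - 1].push_back(i);
  }
  if (root < 0) stop("no root in parent vector");
  // postorder via DFS preorder reversal
  std::vector<int> order;
  order.reserve(n);
  std::vector<int> stack(1, root);
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    order.push_back(u);
    for (int v : kids[u]) stack.push_back(v);
  }
  std::vector<unsigned char> st(static_cast<size_t>(n) * nChar, 0);
  int score = 0;
  for (int oi = n - 1; oi >= 0; --oi) {
    int u = order[oi];
    for (int c = 0; c < nChar; ++c) {
      unsigned char acc = static_cast<unsigned char>(leafMask(u, c));
      for (int v : kids[u]) {
        unsigned char sv = st[static_cast<size_t>(v) * nChar + c];
        if (sv == 0) continue;  // no informative descendants
        if (acc == 0) {
          acc = sv;
        } else {
          unsigned char inter = acc & sv;
          if (inter) acc = inter;
          else { acc |= sv; ++score; }
        }
      }
      st[static_cast<size_t>(u) * nChar + c] = acc;
    }
  }
  return score;
}

namespace {

struct MpSearch {
  int nTip, nChar, maxNodes;
  std::vector<unsigned char> tip;   // nTip x nChar masks
  std::vector<int> ea, eb;          // current edge list
  int best;
  int capTrees;
  std::vector<std::vector<int>> bestTrees;
  bool truncated;

  // Fitch score of the current (partial) tree, rooted at tip 0.
  int fitch() {
    const int nEdge = static_cast<int>(ea.size());
    std::vector<std::vector<int>> adj(maxNodes);
    for (int i = 0; i < nEdge; ++i) {
      adj[ea[i]].push_back(eb[i]);
      adj[eb[i]].push_back(ea[i]);
    }
    std::vector<int> order, parent(maxNodes, -1), stack(1, 0);
    order.reserve(nEdge + 1);
    std::vector<char> seen(maxNodes, 0);
    seen[0] = 1;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      order.push_back(u);
      for (int v : adj[u]) {
        if (!seen[v]) { seen[v] = 1; parent[v] = u; stack.push_back(v); }
      }
    }
    std::vector<unsigned char> st(static_cast<size_t>(maxNodes) * nChar, 0);
    int score = 0;
    for (int oi = static_cast<int>(order.size()) - 1; oi >= 0; --oi) {
      int u = order[oi];
      for (int c = 0; c < nChar; ++c) {
        unsigned char acc =
            (u < nTip) ? tip[static_cast<size_t>(u) * nChar + c] : 0;
        for (int v : adj[u]) {
          if (v == parent[u]) continue;
          unsigned char sv = st[static_cast<size_t>(v) * nChar + c];
          if (acc == 0) {
            acc = sv;
          } else {
            unsigned char inter = acc & sv;
            if (inter) acc = inter;
            else { acc |= sv; ++score; }
          }
        }
        st[static_cast<size_t>(u) * nChar + c] = acc;
      }
    }
    return score;
  }

  void record() {
    int s = fitch();
    if (s < best) {
      best = s;
      bestTrees.clear();
      truncated = false;
    }
    if (s == best) {
      if (static_cast<int>(bestTrees.size()) < capTrees) {
        std::vector<int> tr;
        tr.reserve(ea.size() * 2);
        for (size_t i = 0; i < ea.size(); ++i) {
          tr.push_back(ea[i]);
          tr.push_back(eb[i]);
        }
        bestTrees.push_back(tr);
      } else {
        truncated = true;
      }
    }
  }

  void recurse(int nextTip) {
    if (nextTip == nTip) {
      record();
      return;
    }
    // bound: parsimony score is monotone under taxon addition
    if (fitch() > best) return;
    int newNode = nTip + (nextTip - 2);  // internal ids after tips
    const int nEdge = static_cast<int>(ea.size());
    for (int i = 0; i < nEdge; ++i) {
      int a = ea[i], b = eb[i];
      ea[i] = a; eb[i] = newNode;
      ea.push_back(newNode); eb.push_back(b);
      ea.push_back(newNode); eb.push_back(nextTip);
      recurse(nextTip + 1);
      ea.pop_back(); eb.pop_back();
      ea.pop_back(); eb.pop_back();
      ea[i] = a; eb[i] = b;
    }
  }
};

}  // namespace

// Exact maximum-parsimony search (branch and bound over stepwise insertion)
// for unrooted binary trees on the rows of tipMask (nTip x nChar state
// masks, tip 1 conventionally the all-zero normal outgroup). Returns the
// minimum score and up to capTrees optimal trees as 1-based edge matrices.
// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix tipMask, int capTrees = 64) {
  MpSearch s;
  s.nTip = tipMask.nrow();
  s.nChar = tipMask.ncol();
  s.maxNodes = 2 * s.nTip - 2;
  s.capTrees = capTrees;
  s.truncated = false;
  s.best = INT_MAX;
  s.tip.resize(static_cast<size_t>(s.nTip) * s.nChar);
  for (int i = 0; i < s.nTip; ++i)
    for (int c = 0; c < s.nChar; ++c)
      s.tip[static_cast<size_t>(i) * s.nChar + c] =
          static_cast<unsigned char>(tipMask(i, c));

  if (s.nTip < 2) stop("need >= 2 tips");
  if (s.nTip == 2) {
    s.ea = {0}; s.eb = {1};
    s.record();
  } else {
    // initial tree on tips 0,1,2 around internal node nTip
    s.ea = {0, 1, 2};
    s.eb = {s.nTip, s.nTip, s.nTip};
    s.recurse(3);
  }

  List trees(s.bestTrees.size());
  for (size_t t = 0; t < s.bestTrees.size(); ++t) {
    const std::vector<int>& tr = s.bestTrees[t];
    IntegerMatrix em(static_cast<int>(tr.size() / 2), 2);
    for (size_t i = 0; i < tr.size() / 2; ++i) {
      em(static_cast<int>(i), 0) = tr[2 * i] + 1;
      em(static_cast<int>(i), 1) = tr[2 * i + 1] + 1;
    }
    trees[t] = em;
  }
  return List::create(Named("score") = s.best, Named("trees") = trees,
                      Named("truncated") = s.truncated);
}
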