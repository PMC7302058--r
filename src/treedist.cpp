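// Split-based tree-to-tree distances: Robinson-Foulds symmetric difference
// and the matching split distance (minimum-cost perfect matching between
// split sets, solved exactly with the Hungarian algorithm).  Trees are the
// same edge-list encoding used by the parsimony engine; leaf sets are
// limited to 64 taxa (one machine word per split).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

// splits (side not containing tip 0) of an edge-list tree
std::vector<uint64_t> edgeSplits(const IntegerMatrix& e, int ntip) {
  int maxnode = 0;
  for (int i = 0; i < e.nrow(); ++i)
    maxnode = std::max(maxnode, std::max(e(i, 0), e(i, 1)) + 1);
  std::vector<std::vector<std::pair<int, int> > > adj(maxnode);
  for (int i = 0; i < e.nrow(); ++i) {
    adj[e(i, 0)].push_back(std::make_pair(e(i, 1), i));
    adj[e(i, 1)].push_back(std::make_pair(e(i, 0), i));
  }
  std::vector<int> par(maxnode, -1), paredge(maxnode, -1), order;
  std::vector<char> seen(maxnode, 0);
  int root = adj[0][0].first;
  seen[0] = 1;
  seen[root] = 1;
  paredge[root] = adj[0][0].second;
  order.push_back(root);
  for (size_t qi = 0; qi < order.size(); ++qi) {
    int v = order[qi];
    for (size_t j = 0; j < adj[v].size(); ++j) {
      int w = adj[v][j].first;
      if (seen[w]) continue;
      seen[w] = 1;
      par[w] = v;
      paredge[w] = adj[v][j].second;
      order.push_back(w);
    }
  }
  std::vector<uint64_t> acc(maxnode, 0), below(e.nrow(), 0);
  for (int qi = (int)order.size() - 1; qi >= 0; --qi) {
    int v = order[qi];
    if (v < ntip) acc[v] |= (uint64_t)1 << v;
    below[paredge[v]] = acc[v];
    if (par[v] >= 0) acc[par[v]] |= acc[v];
  }
  std::vector<uint64_t> res;
  for (int i = 0; i < e.nrow(); ++i) {
    int pc = __builtin_popcountll(below[i]);
    if (pc >= 2 && pc <= ntip - 2) res.push_back(below[i]);
  }
  std::sort(res.begin(), res.end());
  res.erase(std::unique(res.begin(), res.end()), res.end());
  return res;
}

int rfDist(const std::vector<uint64_t>& s1, const std::vector<uint64_t>& s2) {
  size_t i = 0, j = 0;
  int common = 0;
  while (i < s1.size() && j < s2.size()) {
    if (s1[i] == s2[j]) { ++common; ++i; ++j; }
    else if (s1[i] < s2[j]) ++i;
    else ++j;
  }
  return (int)(s1.size() + s2.size()) - 2 * common;
}

// Hungarian algorithm (potentials version), square cost matrix, O(n^3)
long hungarian(const std::vector<std::vector<int> >& a) {
  int n = (int)a.size();
  if (n == 0) return 0;
  const long INF = 1e18;
  std::vector<long> u(n + 1, 0), v(n + 1, 0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<long> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      long delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        long cur = a[i0 - 1][j - 1] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  long cost = 0;
  for (int j = 1; j <= n; ++j) cost += a[p[j] - 1][j - 1];
  return cost;
}

// matching split distance between two split sets over ntip leaves
long matchingDist(const std::vector<uint64_t>& s1,
                  const std::vector<uint64_t>& s2, int ntip) {
  int n1 = (int)s1.size(), n2 = (int)s2.size();
  int n = std::max(n1, n2);
  if (n == 0) return 0;
  std::vector<std::vector<int> > cost(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i < n1 && j < n2) {
        int h = __builtin_popcountll(s1[i] ^ s2[j]);
        cost[i][j] = std::min(h, ntip - h);
      } else if (i < n1) {  // dummy on the right: cost min(|A|,|B|)
        int p = __builtin_popcountll(s1[i]);
        cost[i][j] = std::min(p, ntip - p);
      } else if (j < n2) {
        int p = __builtin_popcountll(s2[j]);
        cost[i][j] = std::min(p, ntip - p);
      }  // dummy-dummy: 0
    }
  }
  return hungarian(cost);
}

std::vector<std::vector<uint64_t> > splitsOfList(const List& trees, int ntip) {
  std::vector<std::vector<uint64_t> > out(trees.size());
  for (int i = 0; i < trees.size(); ++i)
    out[i] = edgeSplits(as<IntegerMatrix>(trees[i]), ntip);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".rf_dist_cpp")]]
int rf_dist_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntip) {
  return rfDist(edgeSplits(e1, ntip), edgeSplits(e2, ntip));
}

// [[Rcpp::export(name = ".matching_dist_cpp")]]
double matching_dist_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntip) {
  return (double)matchingDist(edgeSplits(e1, ntip), edgeSplits(e2, ntip), ntip);
}

// pairwise distance matrix between two collections of trees
// metric: 0 = RF, 1 = matching
// [[Rcpp::export(name = ".pair_dist_cpp")]]
NumericMatrix pair_dist_cpp(List treesA, List treesB, int ntip, int metric) {
  std::vector<std::vector<uint64_t> > sa = splitsOfList(treesA, ntip);
  std::vector<std::vector<uint64_t> > sb = splitsOfList(treesB, ntip);
  NumericMatrix d(sa.size(), sb.size());
  for (size_t i = 0; i < sa.size(); ++i)
    for (size_t j = 0; j < sb.size(); ++j)
      d(i, j) = metric == 0 ? (double)rfDist(sa[i], sb[j])
                            : (double)matchingDist(sa[i], sb[j], ntip);
  return d;
}
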