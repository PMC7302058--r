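// Bit-parallel Fitch/Hartigan parsimony scoring and heuristic tree search.
//
// Trees are undirected edge lists over integer node ids: tips 0..ntip-1,
// internal nodes ntip..2*ntip-3 (ids may be permuted after branch surgery
// but always stay below 2*ntip-2).  Character state sets are bitmasks in a
// 32-bit integer, one bit per state; missing/inapplicable cells must be
// pre-expanded by the caller to the full-alphabet mask so that they can
// never force a step.  Scoring uses Hartigan's generalization of the Fitch
// pass, which is exact for unordered characters on arbitrarily
// multifurcating trees.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <functional>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

namespace {

struct Topo {
  std::vector<int> a, b;  // edge endpoints
  int nedge() const { return (int)a.size(); }
  void add(int x, int y) { a.push_back(x); b.push_back(y); }
};

// Scratch buffers shared across many scoring calls.
struct Scorer {
  int ntip, nchar, maxnode;
  std::vector<uint32_t> masks;  // tip-major: masks[t*nchar + c]
  std::vector<int> head, nxt, to;      // adjacency lists over edges*2
  std::vector<int> post, parent, stk;  // traversal
  std::vector<uint32_t> state;         // state[node*nchar + c]
  std::vector<int> kids;

  Scorer(const IntegerMatrix& m) {
    ntip = m.nrow();
    nchar = m.ncol();
    maxnode = 2 * ntip;  // safe upper bound on node ids + 1
    masks.resize((size_t)ntip * nchar);
    for (int t = 0; t < ntip; ++t)
      for (int c = 0; c < nchar; ++c)
        masks[(size_t)t * nchar + c] = (uint32_t)m(t, c);
    head.assign(maxnode, -1);
    parent.assign(maxnode, -1);
    state.resize((size_t)maxnode * nchar);
  }

  // scratch for incremental (view-based) candidate evaluation
  std::vector<uint32_t> upSet, dnSet, fSet;
  std::vector<int> vOrder, vParent, vParEdge, vComp;

  void ensureViewBuffers() {
    if (upSet.empty()) {
      upSet.resize((size_t)maxnode * nchar);
      dnSet.resize((size_t)maxnode * nchar);
      fSet.resize((size_t)maxnode * nchar);
    }
  }

  void buildAdj(const Topo& t) {
    int ne = t.nedge();
    nxt.assign(2 * ne, -1);
    to.assign(2 * ne, -1);
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < ne; ++i) {
      to[2 * i] = t.b[i];
      nxt[2 * i] = head[t.a[i]];
      head[t.a[i]] = 2 * i;
      to[2 * i + 1] = t.a[i];
      nxt[2 * i + 1] = head[t.b[i]];
      head[t.b[i]] = 2 * i + 1;
    }
  }

  // Root at an internal node (any id >= ntip present in the edge set);
  // falls back to node t.a[0] for degenerate 2-tip trees.
  int pickRoot(const Topo& t) {
    for (int i = 0; i < t.nedge(); ++i) {
      if (t.a[i] >= ntip) return t.a[i];
      if (t.b[i] >= ntip) return t.b[i];
    }
    return t.a[0];
  }

  void traverse(const Topo& t, int root) {
    buildAdj(t);
    post.clear();
    stk.clear();
    parent[root] = -1;
    stk.push_back(root);
    while (!stk.empty()) {
      int v = stk.back();
      stk.pop_back();
      post.push_back(v);
      for (int e = head[v]; e != -1; e = nxt[e]) {
        int w = to[e];
        if (w == parent[v]) continue;
        parent[w] = v;
        stk.push_back(w);
      }
    }
    std::reverse(post.begin(), post.end());  // children before parents
  }

  // Total steps, or per-character steps if out != nullptr.  With a
  // non-negative `limit` the pass aborts once the total exceeds it (the
  // returned value is then only guaranteed to be > limit).
  long score(const Topo& t, int* out = nullptr, long limit = -1) {
    int root = pickRoot(t);
    traverse(t, root);
    long total = 0;
    if (out) std::fill(out, out + nchar, 0);
    for (int c = 0; c < nchar; ++c) {
      if (limit >= 0 && total > limit) return total;
      long steps = 0;
      for (size_t pi = 0; pi < post.size(); ++pi) {
        int v = post[pi];
        if (v < ntip) {
          state[(size_t)v * nchar + c] = masks[(size_t)v * nchar + c];
          continue;
        }
        // gather children
        int k = 0;
        uint32_t s0 = 0, s1 = 0, uni = 0;
        kids.clear();
        for (int e = head[v]; e != -1; e = nxt[e]) {
          int w = to[e];
          if (w == parent[v]) continue;
          uint32_t sw = state[(size_t)w * nchar + c];
          if (k == 0) s0 = sw; else if (k == 1) s1 = sw;
          kids.push_back((int)sw);
          uni |= sw;
          ++k;
        }
        uint32_t res;
        if (k == 1) {
          res = s0;
        } else if (k == 2) {
          uint32_t inter = s0 & s1;
          if (inter) res = inter;
          else { res = s0 | s1; ++steps; }
        } else {
          // Hartigan: keep states of maximal child count
          int maxcnt = 0;
          uint32_t sel = 0;
          for (uint32_t bits = uni; bits; bits &= bits - 1) {
            uint32_t bit = bits & (~bits + 1u);
            int cnt = 0;
            for (int j = 0; j < k; ++j)
              if ((uint32_t)kids[j] & bit) ++cnt;
            if (cnt > maxcnt) { maxcnt = cnt; sel = bit; }
            else if (cnt == maxcnt) sel |= bit;
          }
          res = sel;
          steps += k - maxcnt;
        }
        state[(size_t)v * nchar + c] = res;
      }
      if (out) out[c] = (int)steps;
      total += steps;
    }
    return total;
  }
};

// Per-edge "views" of one component of a (possibly bisected) tree: for
// every edge, the Fitch state set of the whole component rooted at a point
// subdividing that edge.  Exact for binary components (Fitch score is
// root-invariant), giving O(nchar) evaluation of any reconnection:
//   len = steps_A + steps_B + #chars{ F_A(eA) & F_B(eB) == 0 }.
struct Views {
  std::vector<std::pair<int, int> > edges;  // (edge index, child node)
  long steps = 0;
  int loneTip = -1;  // component is a single tip (no edges)
};

inline uint32_t fitchOp(uint32_t a, uint32_t b, int& step) {
  uint32_t i = a & b;
  if (i) return i;
  ++step;
  return a | b;
}

long joinCost(int nchar, const uint32_t* FA, const uint32_t* FB) {
  long extra = 0;
  for (int c = 0; c < nchar; ++c)
    if ((FA[c] & FB[c]) == 0u) ++extra;
  return extra;
}

// Fill the views of the component of `start`; sc.buildAdj(topo) must have
// been called for the topology in question.  Components must be binary
// (all internal nodes degree 3), which holds throughout the search.
void computeViews(Scorer& sc, int start, Views& out) {
  out.edges.clear();
  out.steps = 0;
  out.loneTip = -1;
  sc.ensureViewBuffers();
  const int nchar = sc.nchar;
  if (sc.head[start] == -1) { out.loneTip = start; return; }
  std::vector<int> comp;
  std::vector<char> seen(sc.maxnode, 0);
  comp.push_back(start);
  seen[start] = 1;
  for (size_t i = 0; i < comp.size(); ++i)
    for (int e = sc.head[comp[i]]; e != -1; e = sc.nxt[e])
      if (!seen[sc.to[e]]) { seen[sc.to[e]] = 1; comp.push_back(sc.to[e]); }
  int root = -1;
  for (size_t i = 0; i < comp.size() && root < 0; ++i) {
    int deg = 0;
    for (int e = sc.head[comp[i]]; e != -1; e = sc.nxt[e]) ++deg;
    if (deg == 1) root = comp[i];
  }
  std::vector<int> order, parv(sc.maxnode, -1), paredge(sc.maxnode, -1);
  std::vector<int> kids1(sc.maxnode, -1), kids2(sc.maxnode, -1);
  order.push_back(root);
  parv[root] = root;
  for (size_t i = 0; i < order.size(); ++i) {
    int vtx = order[i];
    for (int e = sc.head[vtx]; e != -1; e = sc.nxt[e]) {
      int w = sc.to[e];
      if (w == parv[vtx]) continue;
      parv[w] = vtx;
      paredge[w] = e / 2;
      if (kids1[vtx] < 0) kids1[vtx] = w; else kids2[vtx] = w;
      order.push_back(w);
    }
  }
  // up-pass: Fitch sets of the subtree below each node + total steps
  int steps = 0;
  for (int i = (int)order.size() - 1; i >= 1; --i) {
    int vtx = order[i];
    uint32_t* U = &sc.upSet[(size_t)vtx * nchar];
    if (kids1[vtx] < 0) {
      memcpy(U, &sc.masks[(size_t)vtx * nchar], (size_t)nchar * 4);
    } else {
      const uint32_t* a = &sc.upSet[(size_t)kids1[vtx] * nchar];
      const uint32_t* b = &sc.upSet[(size_t)kids2[vtx] * nchar];
      for (int c = 0; c < nchar; ++c) U[c] = fitchOp(a[c], b[c], steps);
    }
  }
  {
    const uint32_t* rm = &sc.masks[(size_t)root * nchar];
    const uint32_t* uc = &sc.upSet[(size_t)kids1[root] * nchar];
    for (int c = 0; c < nchar; ++c) if ((rm[c] & uc[c]) == 0u) ++steps;
  }
  out.steps = steps;
  // down-pass: sets on the rootward side of each edge, then the full
  // component set F rooted on the edge itself
  int dummy = 0;
  for (size_t i = 1; i < order.size(); ++i) {
    int vtx = order[i];
    int p = parv[vtx];
    uint32_t* D = &sc.dnSet[(size_t)vtx * nchar];
    if (p == root) {
      memcpy(D, &sc.masks[(size_t)root * nchar], (size_t)nchar * 4);
    } else {
      int sib = kids1[p] == vtx ? kids2[p] : kids1[p];
      const uint32_t* us = &sc.upSet[(size_t)sib * nchar];
      const uint32_t* dp = &sc.dnSet[(size_t)p * nchar];
      for (int c = 0; c < nchar; ++c) D[c] = fitchOp(us[c], dp[c], dummy);
    }
    uint32_t* F = &sc.fSet[(size_t)vtx * nchar];
    const uint32_t* U = &sc.upSet[(size_t)vtx * nchar];
    for (int c = 0; c < nchar; ++c) F[c] = fitchOp(U[c], D[c], dummy);
    out.edges.push_back(std::make_pair(paredge[vtx], vtx));
  }
}

Topo topoFromMatrix(const IntegerMatrix& e) {
  Topo t;
  for (int i = 0; i < e.nrow(); ++i) t.add(e(i, 0), e(i, 1));
  return t;
}

IntegerMatrix topoToMatrix(const Topo& t) {
  IntegerMatrix e(t.nedge(), 2);
  for (int i = 0; i < t.nedge(); ++i) { e(i, 0) = t.a[i]; e(i, 1) = t.b[i]; }
  return e;
}

// canonical nontrivial splits (side not containing tip 0) as sorted uint64s;
// requires ntip <= 64
std::vector<uint64_t> topoSplits(const Topo& t, int ntip) {
  int maxnode = 0;
  for (int i = 0; i < t.nedge(); ++i)
    maxnode = std::max(maxnode, std::max(t.a[i], t.b[i]) + 1);
  std::vector<std::vector<std::pair<int, int> > > adj(maxnode);
  for (int i = 0; i < t.nedge(); ++i) {
    adj[t.a[i]].push_back(std::make_pair(t.b[i], i));
    adj[t.b[i]].push_back(std::make_pair(t.a[i], i));
  }
  // postorder from tip 0's neighbor
  std::vector<uint64_t> below(t.nedge(), 0);  // tips below each edge (away from root side)
  std::vector<int> par(maxnode, -1), paredge(maxnode, -1), order;
  int root = adj[0][0].first;
  std::vector<int> stk;
  stk.push_back(root);
  par[root] = 0;
  paredge[root] = adj[0][0].second;
  order.push_back(root);
  std::vector<char> seen(maxnode, 0);
  seen[0] = 1; seen[root] = 1;
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
  std::vector<uint64_t> acc(maxnode, 0);
  for (int qi = (int)order.size() - 1; qi >= 0; --qi) {
    int v = order[qi];
    if (v < ntip) acc[v] |= (uint64_t)1 << v;
    if (par[v] >= 0 || paredge[v] >= 0) {
      below[paredge[v]] = acc[v];
      if (par[v] >= 0) acc[par[v]] |= acc[v];
    }
  }
  std::vector<uint64_t> res;
  for (int i = 0; i < t.nedge(); ++i) {
    int pc = __builtin_popcountll(below[i]);
    if (pc >= 2 && pc <= ntip - 2) res.push_back(below[i]);
  }
  std::sort(res.begin(), res.end());
  res.erase(std::unique(res.begin(), res.end()), res.end());
  return res;
}

// contract edge i (merge endpoint b into a)
Topo contractEdge(const Topo& t, int ei) {
  Topo r;
  int u = t.a[ei], v = t.b[ei];
  for (int i = 0; i < t.nedge(); ++i) {
    if (i == ei) continue;
    int x = t.a[i] == v ? u : t.a[i];
    int y = t.b[i] == v ? u : t.b[i];
    r.add(x, y);
  }
  return r;
}

Topo contractEdges(const Topo& t, const std::vector<char>& drop) {
  // union-find over endpoints of dropped edges
  int maxnode = 0;
  for (int i = 0; i < t.nedge(); ++i)
    maxnode = std::max(maxnode, std::max(t.a[i], t.b[i]) + 1);
  std::vector<int> rep(maxnode);
  for (int i = 0; i < maxnode; ++i) rep[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (rep[x] != x) { rep[x] = rep[rep[x]]; x = rep[x]; }
    return x;
  };
  for (int i = 0; i < t.nedge(); ++i)
    if (drop[i]) rep[find(t.a[i])] = find(t.b[i]);
  Topo r;
  for (int i = 0; i < t.nedge(); ++i) {
    if (drop[i]) continue;
    r.add(find(t.a[i]), find(t.b[i]));
  }
  return r;
}

// Contract internal edges whose minimum length over all optimal
// reconstructions is zero (contract-and-rescore test: the contracted
// tree's score is unchanged exactly when some optimal reconstruction
// assigns both endpoints the same state).  Contractions are applied
// greedily one at a time and re-tested, because two individually
// zero-minimum branches can jointly carry length; the greedy order keeps
// the collapsed tree's parsimony length equal to the optimum.
Topo collapseZero(const Topo& t, Scorer& sc, long base) {
  Topo cur = t;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < cur.nedge(); ++i) {
      if (cur.a[i] < sc.ntip || cur.b[i] < sc.ntip) continue;
      Topo c = contractEdge(cur, i);
      if (sc.score(c) == base) {
        cur = c;
        changed = true;
        break;
      }
    }
  }
  return cur;
}

int randInt(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct HeldTree {
  Topo topo;
  long len;
  double tie;
};

}  // namespace

// [[Rcpp::export(name = ".fitch_steps_cpp")]]
IntegerVector fitch_steps_cpp(IntegerMatrix edges, IntegerMatrix masks) {
  Scorer sc(masks);
  Topo t = topoFromMatrix(edges);
  std::vector<int> out(sc.nchar);
  sc.score(t, out.data());
  return wrap(out);
}

// [[Rcpp::export(name = ".collapse_zero_cpp")]]
IntegerMatrix collapse_zero_cpp(IntegerMatrix edges, IntegerMatrix masks) {
  Scorer sc(masks);
  Topo t = topoFromMatrix(edges);
  long base = sc.score(t);
  Topo r = collapseZero(t, sc, base);
  return topoToMatrix(r);
}

// [[Rcpp::export(name = ".tree_splits_cpp")]]
NumericVector tree_splits_cpp(IntegerMatrix edges, int ntip) {
  Topo t = topoFromMatrix(edges);
  std::vector<uint64_t> s = topoSplits(t, ntip);
  NumericVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    double d;
    memcpy(&d, &s[i], 8);
    out[i] = d;
  }
  return out;
}

// Stepwise addition (random sequences, holding `hold` best partials) with
// TBR branch swapping to a local optimum, pooling equal-best topologies.
// [[Rcpp::export(name = ".heuristic_search_cpp")]]
List heuristic_search_cpp(IntegerMatrix masks, int nadd, int hold,
                          int maxtrees, int swapmax, bool collapse) {
  int ntip = masks.nrow();
  if (ntip < 4) stop("need at least 4 taxa");
  Scorer sc(masks);

  long globalBest = -1;
  std::vector<Topo> pool;
  std::set<std::vector<uint64_t> > poolKeys;

  for (int rep = 0; rep < nadd; ++rep) {
    // random addition order
    std::vector<int> ord(ntip);
    for (int i = 0; i < ntip; ++i) ord[i] = i;
    for (int i = ntip - 1; i > 0; --i) std::swap(ord[i], ord[randInt(i + 1)]);

    std::vector<HeldTree> held(1);
    held[0].topo.add(ord[0], ntip);
    held[0].topo.add(ord[1], ntip);
    held[0].topo.add(ord[2], ntip);
    held[0].len = sc.score(held[0].topo);

    struct Cand { int h; int edge; long len; double tie; };
    auto candLess = [](const Cand& x, const Cand& y) {
      return x.len != y.len ? x.len < y.len : x.tie < y.tie;
    };
    Views vw;
    for (int idx = 3; idx < ntip; ++idx) {
      int tip = ord[idx];
      int newint = ntip + idx - 2;
      const uint32_t* tm = &sc.masks[(size_t)tip * sc.nchar];
      std::vector<Cand> cand;
      long cutoff = -1;  // hold-th best length so far (evaluation bound)
      for (size_t h = 0; h < held.size(); ++h) {
        const Topo& base = held[h].topo;
        sc.buildAdj(base);
        computeViews(sc, base.a[0], vw);
        for (size_t k = 0; k < vw.edges.size(); ++k) {
          const uint32_t* F =
            &sc.fSet[(size_t)vw.edges[k].second * sc.nchar];
          long L = vw.steps + joinCost(sc.nchar, F, tm);
          if (cutoff >= 0 && L > cutoff) continue;
          cand.push_back(Cand{(int)h, vw.edges[k].first, L, unif_rand()});
          if ((int)cand.size() >= hold &&
              (cutoff < 0 || (int)cand.size() >= 4 * hold)) {
            std::sort(cand.begin(), cand.end(), candLess);
            if ((int)cand.size() > hold) cand.resize(hold);
            cutoff = cand.back().len;
          }
        }
      }
      std::sort(cand.begin(), cand.end(), candLess);
      if ((int)cand.size() > hold) cand.resize(hold);
      std::vector<HeldTree> nh;
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const Topo& base = held[cand[ci].h].topo;
        int ei = cand[ci].edge;
        Topo nt;
        for (int j = 0; j < base.nedge(); ++j) {
          if (j == ei) continue;
          nt.add(base.a[j], base.b[j]);
        }
        nt.add(base.a[ei], newint);
        nt.add(newint, base.b[ei]);
        nt.add(newint, tip);
        HeldTree ht;
        ht.topo = nt;
        ht.len = cand[ci].len;
        ht.tie = cand[ci].tie;
        nh.push_back(ht);
      }
      held.swap(nh);
    }

    // TBR from the best held full trees
    long best = held[0].len;
    std::vector<Topo> store;
    std::set<std::vector<uint64_t> > keys;
    for (size_t h = 0; h < held.size(); ++h) {
      if (held[h].len != best) continue;
      std::vector<uint64_t> k = topoSplits(held[h].topo, ntip);
      if (keys.insert(k).second && (int)store.size() < maxtrees)
        store.push_back(held[h].topo);
    }

    size_t nextSwap = 0;
    while (nextSwap < store.size() && nextSwap < (size_t)swapmax) {
      Topo cur = store[nextSwap];
      ++nextSwap;
      bool improved = false;
      // enumerate TBR neighbours of cur
      for (int ei = 0; ei < cur.nedge() && !improved; ++ei) {
        int u = cur.a[ei], v = cur.b[ei];
        // edges minus ei, with degree-2 suppression of u/v where internal
        Topo rest;
        for (int j = 0; j < cur.nedge(); ++j)
          if (j != ei) rest.add(cur.a[j], cur.b[j]);
        std::vector<int> freeIds;
        for (int which = 0; which < 2; ++which) {
          int x = which == 0 ? u : v;
          if (x < ntip) continue;
          // neighbours of x in rest
          std::vector<int> nb, eidx;
          for (int j = 0; j < rest.nedge(); ++j) {
            if (rest.a[j] == x) { nb.push_back(rest.b[j]); eidx.push_back(j); }
            else if (rest.b[j] == x) { nb.push_back(rest.a[j]); eidx.push_back(j); }
          }
          if (nb.size() == 2) {
            // remove both edges, add fused edge
            Topo r2;
            for (int j = 0; j < rest.nedge(); ++j)
              if (j != eidx[0] && j != eidx[1]) r2.add(rest.a[j], rest.b[j]);
            r2.add(nb[0], nb[1]);
            rest = r2;
            freeIds.push_back(x);
          }
        }
        // seeds for the two components: the tip itself, or (for a
        // suppressed internal endpoint) any of its former neighbours
        int seedA = (u < ntip) ? u : -1;
        int seedB = (v < ntip) ? v : -1;
        for (int j = 0; j < cur.nedge() && (seedA < 0 || seedB < 0); ++j) {
          if (j == ei) continue;
          if (seedA < 0) {
            if (cur.a[j] == u) seedA = cur.b[j];
            else if (cur.b[j] == u) seedA = cur.a[j];
          }
          if (seedB < 0) {
            if (cur.a[j] == v) seedB = cur.b[j];
            else if (cur.b[j] == v) seedB = cur.a[j];
          }
        }
        sc.buildAdj(rest);
        Views va, vb;
        computeViews(sc, seedA, va);
        computeViews(sc, seedB, vb);
        long SAB = va.steps + vb.steps;
        size_t nA = va.loneTip >= 0 ? 1 : va.edges.size();
        size_t nB = vb.loneTip >= 0 ? 1 : vb.edges.size();
        for (size_t ia = 0; ia < nA && !improved; ++ia) {
          const uint32_t* FA = va.loneTip >= 0
            ? &sc.masks[(size_t)va.loneTip * sc.nchar]
            : &sc.fSet[(size_t)va.edges[ia].second * sc.nchar];
          for (size_t ib = 0; ib < nB && !improved; ++ib) {
            const uint32_t* FB = vb.loneTip >= 0
              ? &sc.masks[(size_t)vb.loneTip * sc.nchar]
              : &sc.fSet[(size_t)vb.edges[ib].second * sc.nchar];
            long L = SAB + joinCost(sc.nchar, FA, FB);
            if (L > best) continue;
            if (L == best && (int)store.size() >= maxtrees) continue;
            // build the reconnected topology
            Topo nt = rest;
            int idPos = 0;
            int na, nbp;
            if (va.loneTip < 0) {
              int j = va.edges[ia].first;
              na = freeIds.size() > (size_t)idPos ? freeIds[idPos++]
                                                  : 2 * ntip - 2;
              int y = nt.b[j];
              nt.b[j] = na;
              nt.add(na, y);
            } else na = va.loneTip;
            if (vb.loneTip < 0) {
              int j = vb.edges[ib].first;
              nbp = freeIds.size() > (size_t)idPos ? freeIds[idPos++]
                                                   : 2 * ntip - 1;
              int y = nt.b[j];
              nt.b[j] = nbp;
              nt.add(nbp, y);
            } else nbp = vb.loneTip;
            nt.add(na, nbp);
            if (L < best) {
              best = L;
              store.clear();
              keys.clear();
              store.push_back(nt);
              keys.insert(topoSplits(nt, ntip));
              nextSwap = 0;
              improved = true;
            } else if ((int)store.size() < maxtrees) {
              std::vector<uint64_t> k = topoSplits(nt, ntip);
              if (keys.insert(k).second) store.push_back(nt);
            }
          }
        }
      }
    }

    // merge into global pool
    if (globalBest < 0 || best < globalBest) {
      globalBest = best;
      pool.clear();
      poolKeys.clear();
    }
    if (best == globalBest) {
      for (size_t i = 0; i < store.size() && (int)pool.size() < maxtrees; ++i) {
        std::vector<uint64_t> k = topoSplits(store[i], ntip);
        if (poolKeys.insert(k).second) pool.push_back(store[i]);
      }
    }
  }

  if (collapse) {
    std::vector<Topo> out;
    std::set<std::vector<uint64_t> > outKeys;
    for (size_t i = 0; i < pool.size(); ++i) {
      Topo c = collapseZero(pool[i], sc, globalBest);
      std::vector<uint64_t> k = topoSplits(c, ntip);
      if (outKeys.insert(k).second) out.push_back(c);
    }
    pool.swap(out);
  }

  List trees(pool.size());
  for (size_t i = 0; i < pool.size(); ++i) trees[i] = topoToMatrix(pool[i]);
  return List::create(_["score"] = (double)globalBest, _["trees"] = trees);
}
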