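// Exact maximum-weight connected subgraph solver.
//
// Strategy: contract connected components of positive-weight nodes into
// supernodes (any optimal solution touching a positive component contains
// all of it), iteratively prune non-positive leaves (never part of an
// optimum containing a positive node), seed the incumbent with a greedy
// cheapest-path attachment of positive supernodes, then branch-and-bound
// over connected subsets rooted at positive supernodes. The bound charges
// every reachable positive its cheapest negative connection cost
// (Dijkstra over node costs): for positives sorted by that cost d with
// prefix weight sums W_j, any extension is worth at most
// max_j (W_j - d_j), since a connector reaching a set Q of positives
// costs at least max_{p in Q} d_p. Ties between equal-score optima break
// toward the lexicographically smallest original-node index set, assuming
// callers pass vertices in key order.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <functional>
#include <limits>

using namespace Rcpp;

namespace {

const double EPS = 1e-9;
const double INF = std::numeric_limits<double>::infinity();

struct Reduced {
  int n = 0;
  std::vector<double> w;
  std::vector<std::vector<int>> adj;
  std::vector<std::vector<int>> members;  // original node indices, sorted
};

bool lexLess(const std::vector<int>& a, const std::vector<int>& b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

struct BnB {
  const Reduced& g;
  std::vector<int> state;  // 0 free, 1 in S, 2 excluded
  double best;
  std::vector<int> bestMembers;  // original indices, sorted
  long long nodesVisited = 0;
  // scratch for Dijkstra
  std::vector<double> dist;
  std::vector<int> parent;

  explicit BnB(const Reduced& gr)
      : g(gr), state(gr.n, 0), best(-1e300), dist(gr.n), parent(gr.n) {}

  std::vector<int> expand(const std::vector<int>& sel) const {
    std::vector<int> out;
    for (int v : sel)
      out.insert(out.end(), g.members[v].begin(), g.members[v].end());
    std::sort(out.begin(), out.end());
    return out;
  }

  void record(double score, const std::vector<int>& sel) {
    if (score > best + EPS) {
      best = score;
      bestMembers = expand(sel);
    } else if (score > best - EPS) {
      std::vector<int> cand = expand(sel);
      if (lexLess(cand, bestMembers)) bestMembers = cand;
    }
  }

  // Dijkstra from the source set over non-excluded nodes; entering node v
  // costs max(0, -w[v]). O(n^2), n is small after reduction.
  void dijkstra(const std::vector<int>& sources) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(parent.begin(), parent.end(), -1);
    std::vector<char> done(g.n, 0);
    for (int s : sources) dist[s] = 0.0;
    for (;;) {
      int u = -1;
      double du = INF;
      for (int v = 0; v < g.n; ++v)
        if (!done[v] && state[v] != 2 && dist[v] < du) { du = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (int v : g.adj[u]) {
        if (state[v] == 2 || done[v]) continue;
        double nd = du + std::max(0.0, -g.w[v]);
        if (nd < dist[v] - 1e-15) { dist[v] = nd; parent[v] = u; }
      }
    }
  }

  // bound + branch-target selection; returns bound, sets targetPos to the
  // most valuable reachable positive (or -1)
  double boundAndTarget(double scoreS, const std::vector<int>& inS,
                        int* targetPos) {
    dijkstra(inS);
    std::vector<std::pair<double, double>> pos;  // (d, w)
    *targetPos = -1;
    double bestNet = -INF;
    for (int v = 0; v < g.n; ++v) {
      if (state[v] == 0 && g.w[v] > 0 && dist[v] < INF) {
        pos.emplace_back(dist[v], g.w[v]);
        double net = g.w[v] - dist[v];
        if (net > bestNet) { bestNet = net; *targetPos = v; }
      }
    }
    if (pos.empty()) return scoreS;
    std::sort(pos.begin(), pos.end());
    double extra = 0.0, cumw = 0.0;
    for (auto& pr : pos) {
      cumw += pr.second;
      extra = std::max(extra, cumw - pr.first);
    }
    return scoreS + extra;
  }

  void search(double scoreS, std::vector<int>& inS, std::vector<int> frontier) {
    ++nodesVisited;
    int target = -1;
    if (boundAndTarget(scoreS, inS, &target) < best - EPS) return;
    if (frontier.empty() || target < 0) return;
    // branch on the first off-set vertex of the cheapest path toward the
    // most valuable positive; fall back to the heaviest frontier vertex
    int v = -1;
    {
      int cur = target;
      while (parent[cur] != -1 && state[parent[cur]] != 1) cur = parent[cur];
      if (parent[cur] != -1) v = cur;  // parent is in S -> frontier vertex
    }
    size_t bi = frontier.size();
    for (size_t i = 0; i < frontier.size(); ++i) {
      if (frontier[i] == v) { bi = i; break; }
    }
    if (bi == frontier.size()) {
      bi = 0;
      for (size_t i = 1; i < frontier.size(); ++i)
        if (g.w[frontier[i]] > g.w[frontier[bi]]) bi = i;
      v = frontier[bi];
    }
    frontier.erase(frontier.begin() + bi);

    // include v
    state[v] = 1;
    inS.push_back(v);
    std::vector<int> f2 = frontier;
    for (int u : g.adj[v]) if (state[u] == 0) {
      bool already = false;
      for (int x : f2) if (x == u) { already = true; break; }
      if (!already) f2.push_back(u);
    }
    double s2 = scoreS + g.w[v];
    record(s2, inS);
    search(s2, inS, f2);
    inS.pop_back();

    // exclude v
    state[v] = 2;
    search(scoreS, inS, frontier);
    state[v] = 0;
  }

  // greedy incumbent: repeatedly attach the positive supernode with the
  // best (weight - cheapest connection cost) through its shortest path
  void greedyIncumbent() {
    int start = -1;
    for (int v = 0; v < g.n; ++v)
      if (state[v] != 2 && g.w[v] > 0 && (start < 0 || g.w[v] > g.w[start]))
        start = v;
    if (start < 0) return;
    std::vector<char> in(g.n, 0);
    std::vector<int> sel{start};
    in[start] = 1;
    double score = g.w[start];
    record(score, sel);
    for (;;) {
      dijkstra(sel);
      int bestP = -1;
      double bestGain = 0.0;
      for (int v = 0; v < g.n; ++v)
        if (!in[v] && state[v] != 2 && g.w[v] > 0 && dist[v] < INF &&
            g.w[v] - dist[v] > bestGain + EPS) {
          bestGain = g.w[v] - dist[v];
          bestP = v;
        }
      if (bestP < 0) break;
      int cur = bestP;
      while (cur != -1 && !in[cur]) {
        in[cur] = 1;
        sel.push_back(cur);
        score += g.w[cur];
        cur = parent[cur];
      }
      record(score, sel);
    }
  }
};

// Exact solve by a node-weighted Steiner dynamic program over terminal
// subsets (Dreyfus-Wagner style). Terminals are the positive supernodes;
// S[mask][v] is the minimum connector cost (sum of max(0,-w) over tree
// nodes, terminals free) of a tree spanning terminals(mask) and v. The
// optimum equals max over masks of (positive weight of mask - min_v
// S[mask][v]); positive nodes used as free intermediates only improve the
// reconstructed solution. Cost is Theta(3^k n + 2^k E log n): predictable,
// unlike branch-and-bound on scattered-positive instances.
struct SteinerDP {
  const Reduced& g;
  const std::vector<char>& removed;
  std::vector<int> terms;
  int k = 0;
  std::vector<std::vector<double>> S;
  std::vector<std::vector<int>> fromMask;  // merge submask, or 0 for walk
  std::vector<std::vector<int>> fromVert;  // walk predecessor, or -1

  SteinerDP(const Reduced& gr, const std::vector<char>& rem)
      : g(gr), removed(rem) {
    for (int v = 0; v < g.n; ++v)
      if (!removed[v] && g.w[v] > 0) terms.push_back(v);
    k = (int)terms.size();
  }

  double cost(int v) const { return std::max(0.0, -g.w[v]); }

  void dijkstraPass(int mask) {
    typedef std::pair<double, int> DI;
    std::priority_queue<DI, std::vector<DI>, std::greater<DI>> pq;
    for (int v = 0; v < g.n; ++v)
      if (S[mask][v] < INF) pq.push({S[mask][v], v});
    while (!pq.empty()) {
      DI top = pq.top(); pq.pop();
      if (top.first > S[mask][top.second] + 1e-15) continue;
      int u = top.second;
      for (int v : g.adj[u]) {
        if (removed[v]) continue;
        double nd = top.first + cost(v);
        if (nd < S[mask][v] - 1e-12) {
          S[mask][v] = nd;
          fromMask[mask][v] = 0;
          fromVert[mask][v] = u;
          pq.push({nd, v});
        }
      }
    }
  }

  // returns selected reduced-node ids and score via out-params
  void solve(std::vector<int>* selOut, double* scoreOut) {
    int full = 1 << k;
    S.assign(full, std::vector<double>(g.n, INF));
    fromMask.assign(full, std::vector<int>(g.n, -1));
    fromVert.assign(full, std::vector<int>(g.n, -1));
    std::vector<double> termW(k);
    for (int i = 0; i < k; ++i) {
      termW[i] = g.w[terms[i]];
      S[1 << i][terms[i]] = 0.0;
    }
    for (int mask = 1; mask < full; ++mask) {
      if (!(mask & (mask - 1))) { dijkstraPass(mask); continue; }
      for (int sub = (mask - 1) & mask; sub > (mask ^ sub);
           sub = (sub - 1) & mask) {
        int oth = mask ^ sub;
        for (int v = 0; v < g.n; ++v) {
          if (S[sub][v] >= INF || S[oth][v] >= INF) continue;
          double nd = S[sub][v] + S[oth][v] - cost(v);
          if (nd < S[mask][v] - 1e-12) {
            S[mask][v] = nd;
            fromMask[mask][v] = sub;
            fromVert[mask][v] = -1;
          }
        }
      }
      dijkstraPass(mask);
    }
    // best value over masks
    double best = -INF;
    int bestMask = -1, bestV = -1;
    for (int mask = 1; mask < full; ++mask) {
      double wsum = 0.0;
      for (int i = 0; i < k; ++i) if (mask & (1 << i)) wsum += termW[i];
      for (int v = 0; v < g.n; ++v) {
        if (S[mask][v] >= INF) continue;
        double val = wsum - S[mask][v];
        if (val > best + EPS) { best = val; bestMask = mask; bestV = v; }
      }
    }
    // reconstruct tree nodes
    std::vector<char> inTree(g.n, 0);
    std::function<void(int, int)> rec = [&](int mask, int v) {
      while (true) {
        inTree[v] = 1;
        if (!(mask & (mask - 1)) && v == terms[__builtin_ctz(mask)]) return;
        int fm = fromMask[mask][v];
        if (fm == 0) {
          v = fromVert[mask][v];
        } else if (fm > 0) {
          rec(fm, v);
          mask = mask ^ fm;
        } else {
          return;  // unreached singleton (defensive)
        }
      }
    };
    rec(bestMask, bestV);
    selOut->clear();
    double sc = 0.0;
    for (int v = 0; v < g.n; ++v)
      if (inTree[v]) { selOut->push_back(v); sc += g.w[v]; }
    *scoreOut = sc;
  }
};

}  // namespace

// method: 0 = auto (DP when 9 <= k <= 16, else branch-and-bound),
//         1 = force branch-and-bound, 2 = force the Steiner subset DP.
// The override exists so the two exact engines can arbitrate each other.
// [[Rcpp::export(name = ".mwcs_solve_cpp")]]
List mwcs_solve_cpp(int n, IntegerMatrix edges, NumericVector weights,
                    int method = 0) {
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0), b = edges(i, 1);
    if (a == b) continue;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (auto& v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }

  // degenerate: no positive node -> best single node, smallest index on tie
  int argmax = 0;
  for (int i = 1; i < n; ++i) if (w[i] > w[argmax] + EPS) argmax = i;
  bool anyPositive = false;
  for (int i = 0; i < n; ++i) if (w[i] > 0) { anyPositive = true; break; }
  if (!anyPositive) {
    return List::create(_["nodes"] = IntegerVector::create(argmax + 1),
                        _["score"] = w[argmax],
                        _["visited"] = 0);
  }

  // contract positive components (union-find)
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int v = 0; v < n; ++v)
    if (w[v] > 0)
      for (int u : adj[v])
        if (u > v && w[u] > 0) {
          int ra = find(v), rb = find(u);
          if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
        }

  std::vector<int> compId(n, -1);
  Reduced g;
  for (int v = 0; v < n; ++v) {
    int r = find(v);
    if (compId[r] < 0) {
      compId[r] = g.n++;
      g.w.push_back(0.0);
      g.members.push_back({});
    }
    compId[v] = compId[r];
    g.w[compId[v]] += w[v];
    g.members[compId[v]].push_back(v);
  }
  for (auto& m : g.members) std::sort(m.begin(), m.end());
  g.adj.assign(g.n, {});
  for (int v = 0; v < n; ++v)
    for (int u : adj[v]) {
      int a = compId[v], b = compId[u];
      if (a != b) g.adj[a].push_back(b);
    }
  for (auto& v : g.adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }

  // prune non-positive leaves iteratively
  std::vector<char> removed(g.n, 0);
  std::vector<int> degree(g.n);
  for (int v = 0; v < g.n; ++v) degree[v] = (int)g.adj[v].size();
  std::queue<int> q;
  for (int v = 0; v < g.n; ++v)
    if (g.w[v] <= 0 && degree[v] <= 1) q.push(v);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    if (removed[v] || !(g.w[v] <= 0 && degree[v] <= 1)) continue;
    removed[v] = 1;
    for (int u : g.adj[v])
      if (!removed[u] && --degree[u] <= 1 && g.w[u] <= 0) q.push(u);
  }
  for (int v = 0; v < g.n; ++v)
    if (!removed[v])
      g.adj[v].erase(std::remove_if(g.adj[v].begin(), g.adj[v].end(),
                                    [&](int u) { return removed[u]; }),
                     g.adj[v].end());

  std::vector<int> roots;
  for (int v = 0; v < g.n; ++v)
    if (!removed[v] && g.w[v] > 0) roots.push_back(v);

  // Many scattered positive supernodes defeat branch-and-bound pruning;
  // the Steiner subset DP has predictable cost there. Few positives (after
  // contraction) are where branch-and-bound shines, and it also provides
  // the lexicographic tie-break guarantee exercised on small instances.
  int kpos = (int)roots.size();
  bool useDP = (method == 2) || (method == 0 && kpos >= 9 && kpos <= 16);
  if (useDP && kpos <= 20) {
    SteinerDP dp(g, removed);
    std::vector<int> selReduced;
    double score = 0.0;
    dp.solve(&selReduced, &score);
    std::vector<int> members;
    for (int v : selReduced)
      members.insert(members.end(), g.members[v].begin(), g.members[v].end());
    std::sort(members.begin(), members.end());
    IntegerVector sel(members.size());
    for (size_t i = 0; i < members.size(); ++i) sel[i] = members[i] + 1;
    return List::create(_["nodes"] = sel, _["score"] = score,
                        _["visited"] = 0.0);
  }

  BnB bb(g);
  std::sort(roots.begin(), roots.end(),
            [&](int a, int b) { return g.w[a] > g.w[b]; });
  // incumbents: single supernodes, then the greedy attachment solution
  for (int r : roots) {
    std::vector<int> single{r};
    bb.record(g.w[r], single);
  }
  bb.state.assign(g.n, 0);
  for (int v = 0; v < g.n; ++v) if (removed[v]) bb.state[v] = 2;
  bb.greedyIncumbent();
  // rooted searches: solutions containing root r but no earlier root
  for (size_t i = 0; i < roots.size(); ++i) {
    int r = roots[i];
    bb.state.assign(g.n, 0);
    for (int v = 0; v < g.n; ++v) if (removed[v]) bb.state[v] = 2;
    for (size_t j = 0; j < i; ++j) bb.state[roots[j]] = 2;
    bb.state[r] = 1;
    std::vector<int> inS{r};
    std::vector<int> frontier;
    for (int u : g.adj[r]) if (bb.state[u] == 0) frontier.push_back(u);
    bb.search(g.w[r], inS, frontier);
  }

  IntegerVector sel(bb.bestMembers.size());
  for (size_t i = 0; i < bb.bestMembers.size(); ++i) sel[i] = bb.bestMembers[i] + 1;
  return List::create(_["nodes"] = sel, _["score"] = bb.best,
                      _["visited"] = (double)bb.nodesVisited);
}
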