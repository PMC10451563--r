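// Compiled core of the ant-colony structure search: K2 local scoring with a
// per-dataset cache, mutual-information-weighted heuristics, arc-by-arc
// network construction under the pseudo-random proportional rule, add /
// delete / reverse hill climbing, and the pheromone update rules.
//
// All level codes are 0-based; node indices crossing the R boundary are
// 1-based and converted at the interface functions.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <map>
#include <tuple>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// splitmix64: tiny, deterministic, platform-independent. Per-ant streams are
// seeded from (colony seed, iteration, ant index) so results do not depend on
// the order in which ants or colonies are executed.
static inline uint64_t sm64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ull;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebull;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() { return sm64(state += 0x9e3779b97f4a7c15ull); }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline uint64_t mix2(uint64_t a, uint64_t b) {
  return sm64(a * 0x9e3779b97f4a7c15ull + b + 0x632be59bd9b4e019ull);
}

// --------------------------------------------------------------- data -----
struct Data {
  const int* lev;  // column-major m x v, 0-based levels
  int m, v;
  const int* cards;
  std::vector<double> lgam;  // lgam[k] = lgamma(k), k <= m + max cardinality

  void build_table() {
    int maxc = 2;
    for (int j = 0; j < v; ++j) maxc = std::max(maxc, cards[j]);
    lgam.resize((size_t)m + maxc + 2);
    for (size_t k = 0; k < lgam.size(); ++k)
      lgam[k] = std::lgamma((double)k);
  }
};

// ------------------------------------------------------ K2 local score ----
// log of the child's factor of the K2 metric:
//   sum_j [ lgamma(r) - lgamma(N_ij + r) + sum_k lgamma(N_ijk + 1) ]
// where j ranges over the parent configurations realized in the data
// (unrealized configurations contribute exactly 0 in log space).
static double k2_local(const Data& d, int child,
                       const std::vector<uint16_t>& pa) {
  const int r = d.cards[child];
  const int* ccol = d.lev + (size_t)child * d.m;
  const double lgr = d.lgam[r];
  std::vector<int> cnt(r, 0);

  if (pa.empty()) {
    for (int s = 0; s < d.m; ++s) cnt[ccol[s]]++;
    double sc = lgr - d.lgam[d.m + r];
    for (int k = 0; k < r; ++k) sc += d.lgam[cnt[k] + 1];
    return sc;
  }

  // encode each sample's parent configuration; mixed-radix when it fits in
  // 62 bits, otherwise an order-preserving id map on the raw config vectors
  std::vector<uint64_t> code(d.m);
  double bits = 0.0;
  for (uint16_t p : pa) bits += std::log2((double)d.cards[p]);
  if (bits < 62.0) {
    for (int s = 0; s < d.m; ++s) {
      uint64_t c = 0;
      for (uint16_t p : pa)
        c = c * (uint64_t)d.cards[p] + (uint64_t)d.lev[(size_t)p * d.m + s];
      code[s] = c;
    }
  } else {
    std::map<std::vector<int>, uint64_t> ids;
    std::vector<int> cfg(pa.size());
    for (int s = 0; s < d.m; ++s) {
      for (size_t t = 0; t < pa.size(); ++t)
        cfg[t] = d.lev[(size_t)pa[t] * d.m + s];
      auto it = ids.emplace(cfg, (uint64_t)ids.size()).first;
      code[s] = it->second;
    }
  }

  std::vector<int> idx(d.m);
  for (int s = 0; s < d.m; ++s) idx[s] = s;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return code[a] < code[b]; });

  double sc = 0.0;
  int i = 0;
  while (i < d.m) {
    int j = i;
    std::fill(cnt.begin(), cnt.end(), 0);
    const uint64_t c0 = code[idx[i]];
    while (j < d.m && code[idx[j]] == c0) { cnt[ccol[idx[j]]]++; ++j; }
    sc += lgr - d.lgam[(j - i) + r];
    for (int k = 0; k < r; ++k) sc += d.lgam[cnt[k] + 1];
    i = j;
  }
  return sc;
}

// ---------------------------------------------------------- score cache ---
struct PaKey {
  int child;
  std::vector<uint16_t> pa;  // sorted ascending
  bool operator==(const PaKey& o) const {
    return child == o.child && pa == o.pa;
  }
};
struct PaKeyHash {
  size_t operator()(const PaKey& k) const {
    uint64_t h = 1469598103934665603ull ^ (uint64_t)(k.child + 1);
    for (uint16_t p : k.pa)
      h = (h ^ (uint64_t)(p + 1)) * 1099511628211ull;
    return (size_t)sm64(h);
  }
};

struct Cache {
  std::unordered_map<PaKey, double, PaKeyHash> map;
  long long hits = 0, misses = 0;
  // bound on stored entries: beyond it, scores are recomputed rather than
  // inserted (a cached value never differs from recomputation, so the cap
  // only affects speed and memory, never results)
  size_t cap = 1500000;
};

static double score_cached(const Data& d, Cache* cache, int child,
                           const std::vector<uint16_t>& pa) {
  if (!cache) return k2_local(d, child, pa);
  PaKey key{child, pa};
  auto it = cache->map.find(key);
  if (it != cache->map.end()) { cache->hits++; return it->second; }
  double sc = k2_local(d, child, pa);
  if (cache->map.size() < cache->cap) cache->map.emplace(std::move(key), sc);
  cache->misses++;
  return sc;
}

// --------------------------------------------------------------- graph ----
struct Graph {
  int v, words;
  std::vector<std::vector<uint16_t>> pa;  // sorted parent sets
  std::vector<std::vector<uint16_t>> ch;  // child lists (unsorted)
  std::vector<uint64_t> reach;            // row a: bitset of nodes a reaches

  explicit Graph(int v_) : v(v_), words((v_ + 63) / 64), pa(v_), ch(v_),
                           reach((size_t)v_ * ((v_ + 63) / 64), 0) {}

  bool has(int u, int c) const {
    return std::binary_search(pa[c].begin(), pa[c].end(), (uint16_t)u);
  }
  bool reaches(int a, int b) const {
    return (reach[(size_t)a * words + (b >> 6)] >> (b & 63)) & 1ull;
  }
  // add u -> c and maintain transitive reachability (construction path)
  void add_reach(int u, int c) {
    add_plain(u, c);
    std::vector<uint64_t> R(reach.begin() + (size_t)c * words,
                            reach.begin() + (size_t)(c + 1) * words);
    R[c >> 6] |= 1ull << (c & 63);
    for (int a = 0; a < v; ++a) {
      if (a == u || reaches(a, u)) {
        uint64_t* row = &reach[(size_t)a * words];
        for (int w = 0; w < words; ++w) row[w] |= R[w];
      }
    }
  }
  void add_plain(int u, int c) {
    auto& p = pa[c];
    p.insert(std::upper_bound(p.begin(), p.end(), (uint16_t)u), (uint16_t)u);
    ch[u].push_back((uint16_t)c);
  }
  void remove_plain(int u, int c) {
    auto& p = pa[c];
    p.erase(std::lower_bound(p.begin(), p.end(), (uint16_t)u));
    auto& k = ch[u];
    k.erase(std::find(k.begin(), k.end(), (uint16_t)c));
  }
  // DFS: does a directed path from -> to exist? (used after deletions, when
  // the incremental reachability rows are stale)
  bool path(int from, int to) const {
    if (from == to) return true;
    std::vector<char> seen(v, 0);
    std::vector<int> stack{from};
    seen[from] = 1;
    while (!stack.empty()) {
      int n = stack.back(); stack.pop_back();
      for (uint16_t c : ch[n]) {
        if (c == to) return true;
        if (!seen[c]) { seen[c] = 1; stack.push_back(c); }
      }
    }
    return false;
  }
};

static std::vector<uint16_t> with_parent(const std::vector<uint16_t>& pa,
                                         int u) {
  std::vector<uint16_t> out(pa);
  out.insert(std::upper_bound(out.begin(), out.end(), (uint16_t)u),
             (uint16_t)u);
  return out;
}
static std::vector<uint16_t> without_parent(const std::vector<uint16_t>& pa,
                                            int u) {
  std::vector<uint16_t> out(pa);
  out.erase(std::lower_bound(out.begin(), out.end(), (uint16_t)u));
  return out;
}

// network score: sum of local scores in node-index order (matches the R-side
// summation order exactly)
static double graph_score(const Data& d, Cache* cache, const Graph& g) {
  double s = 0.0;
  for (int c = 0; c < g.v; ++c) s += score_cached(d, cache, c, g.pa[c]);
  return s;
}

// ---------------------------------------------------------- parameters ----
struct Cfg {
  double alpha, beta, rho, q0, tau0;
  int ants, lstep;
};

static Cfg cfg_from_list(List cfg) {
  Cfg c;
  c.alpha = as<double>(cfg["alpha"]);
  c.beta = as<double>(cfg["beta"]);
  c.rho = as<double>(cfg["rho"]);
  c.q0 = as<double>(cfg["q0"]);
  c.tau0 = as<double>(cfg["tau0"]);
  c.ants = as<int>(cfg["ants"]);
  c.lstep = as<int>(cfg["lstep"]);
  return c;
}

// ---------------------------------------------------------- construction --
// One ant: start from the empty network, repeatedly pick an arc from the
// candidate set (heuristic > 0, acyclic) by the pseudo-random proportional
// rule, apply the local pheromone update, until no candidate remains.
// tau is the colony-shared pheromone (row u, col c for arc u -> c), modified
// in place by the local updates.
static Graph construct_one(const Data& d, Cache* cache,
                           const double* mi, double* tau,
                           const Cfg& cfg, Rng& rng) {
  const int v = d.v;
  Graph g(v);
  std::vector<double> delta((size_t)v * v, 0.0);
  std::vector<double> etaB((size_t)v * v, 0.0);

  // column-major (u, c) cell, matching R's matrix layout for tau and mi
  auto at = [v](int u, int c) -> size_t { return (size_t)c * v + u; };

  auto recompute_child = [&](int c) {
    const double base = score_cached(d, cache, c, g.pa[c]);
    for (int u = 0; u < v; ++u) {
      if (u == c || g.has(u, c)) continue;
      const double dd =
          score_cached(d, cache, c, with_parent(g.pa[c], u)) - base;
      delta[at(u, c)] = dd;
      etaB[at(u, c)] =
          dd > 0.0 ? std::pow((1.0 + mi[at(u, c)]) * dd, cfg.beta) : 0.0;
    }
  };
  for (int c = 0; c < v; ++c) recompute_child(c);

  std::vector<int> cand_u, cand_c;
  std::vector<double> cand_w;
  while (true) {
    const double q = rng.unif();
    int bu = -1, bc = -1;
    if (q <= cfg.q0) {
      // exploitation: argmax tau * eta^beta, ties to smallest (u, c)
      double best = -1.0;
      for (int u = 0; u < v; ++u) {
        for (int c = 0; c < v; ++c) {
          if (u == c || delta[at(u, c)] <= 0.0 || g.has(u, c)) continue;
          if (g.reaches(c, u)) continue;  // adding u -> c would close a cycle
          const double val = tau[at(u, c)] * etaB[at(u, c)];
          if (val > best) { best = val; bu = u; bc = c; }
        }
      }
      if (bu < 0) break;
    } else {
      // exploration: sample proportional to tau^alpha * eta^beta
      cand_u.clear(); cand_c.clear(); cand_w.clear();
      double tot = 0.0;
      for (int u = 0; u < v; ++u) {
        for (int c = 0; c < v; ++c) {
          if (u == c || delta[at(u, c)] <= 0.0 || g.has(u, c)) continue;
          if (g.reaches(c, u)) continue;
          const double w = std::pow(tau[at(u, c)], cfg.alpha) * etaB[at(u, c)];
          cand_u.push_back(u); cand_c.push_back(c); cand_w.push_back(w);
          tot += w;
        }
      }
      if (cand_w.empty()) break;
      double r = rng.unif() * tot;
      size_t pick = cand_w.size() - 1;
      for (size_t i = 0; i < cand_w.size(); ++i) {
        r -= cand_w[i];
        if (r <= 0.0) { pick = i; break; }
      }
      bu = cand_u[pick]; bc = cand_c[pick];
    }
    g.add_reach(bu, bc);
    // local pheromone update on the selected arc
    tau[at(bu, bc)] =
        (1.0 - cfg.rho) * tau[at(bu, bc)] + cfg.rho * cfg.tau0;
    recompute_child(bc);
  }
  return g;
}

// ---------------------------------------------------------- local search --
// First-improvement hill climbing over single-arc additions, deletions and
// reversals; sweeps until no move improves or lstep sweeps are exhausted.
static void local_search(const Data& d, Cache* cache, Graph& g, int lstep) {
  const int v = d.v;
  for (int sweep = 0; sweep < lstep; ++sweep) {
    bool improved = false;
    for (int u = 0; u < v; ++u) {
      for (int c = 0; c < v; ++c) {
        if (u == c) continue;
        if (g.has(u, c)) {
          const double base = score_cached(d, cache, c, g.pa[c]);
          const double del =
              score_cached(d, cache, c, without_parent(g.pa[c], u)) - base;
          if (del > 0.0) {
            g.remove_plain(u, c);
            improved = true;
            continue;
          }
          if (!g.has(c, u)) {
            // reversal u -> c  =>  c -> u; acyclic iff no other u ~> c path
            g.remove_plain(u, c);
            if (!g.path(u, c)) {
              const double gain =
                  del + score_cached(d, cache, u, with_parent(g.pa[u], c)) -
                  score_cached(d, cache, u, g.pa[u]);
              if (gain > 0.0) {
                g.add_plain(c, u);
                improved = true;
                continue;
              }
            }
            g.add_plain(u, c);  // undo tentative removal
          }
        } else {
          if (g.has(c, u) || g.path(c, u)) continue;
          const double add =
              score_cached(d, cache, c, with_parent(g.pa[c], u)) -
              score_cached(d, cache, c, g.pa[c]);
          if (add > 0.0) {
            g.add_plain(u, c);
            improved = true;
          }
        }
      }
    }
    if (!improved) break;
  }
}

// ------------------------------------------------------- R conversions ----
static Graph graph_from_list(List parents, int v) {
  Graph g(v);
  for (int c = 0; c < v; ++c) {
    IntegerVector p = parents[c];
    for (int i = 0; i < p.size(); ++i) g.add_plain(p[i] - 1, c);
  }
  return g;
}

static List graph_to_list(const Graph& g) {
  List out(g.v);
  for (int c = 0; c < g.v; ++c) {
    IntegerVector p(g.pa[c].size());
    for (size_t i = 0; i < g.pa[c].size(); ++i) p[i] = g.pa[c][i] + 1;
    out[c] = p;
  }
  return out;
}

static Data data_from_r(const IntegerMatrix& levels,
                        const IntegerVector& cards) {
  Data d;
  d.lev = INTEGER(levels);
  d.m = levels.nrow();
  d.v = levels.ncol();
  d.cards = INTEGER(cards);
  d.build_table();
  return d;
}

static Cache* cache_from_sexp(SEXP cache_ptr) {
  if (Rf_isNull(cache_ptr)) return nullptr;
  XPtr<Cache> xp(cache_ptr);
  return xp.get();
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
SEXP cache_new_cpp() {
  return XPtr<Cache>(new Cache(), true);
}

// [[Rcpp::export]]
NumericVector cache_stats_cpp(SEXP cache_ptr) {
  Cache* c = cache_from_sexp(cache_ptr);
  if (!c) return NumericVector::create(_["size"] = 0, _["hits"] = 0,
                                       _["misses"] = 0);
  return NumericVector::create(_["size"] = (double)c->map.size(),
                               _["hits"] = (double)c->hits,
                               _["misses"] = (double)c->misses);
}

// [[Rcpp::export]]
double k2_local_cpp(IntegerMatrix levels, IntegerVector cards, int child,
                    IntegerVector parents, SEXP cache_ptr) {
  Data d = data_from_r(levels, cards);
  std::vector<uint16_t> pa(parents.size());
  for (int i = 0; i < parents.size(); ++i) pa[i] = (uint16_t)(parents[i] - 1);
  std::sort(pa.begin(), pa.end());
  return score_cached(d, cache_from_sexp(cache_ptr), child - 1, pa);
}

// [[Rcpp::export]]
List construct_cbn_cpp(IntegerMatrix levels, IntegerVector cards,
                       NumericMatrix mi, NumericMatrix tau, List cfg_list,
                       double seed, SEXP cache_ptr) {
  Data d = data_from_r(levels, cards);
  Cfg cfg = cfg_from_list(cfg_list);
  Cache* cache = cache_from_sexp(cache_ptr);
  NumericMatrix tau_out = clone(tau);
  Rng rng((uint64_t)seed);
  Graph g = construct_one(d, cache, REAL(mi), REAL(tau_out), cfg, rng);
  return List::create(_["parents"] = graph_to_list(g),
                      _["score"] = graph_score(d, cache, g),
                      _["tau"] = tau_out);
}

// [[Rcpp::export]]
List local_search_cpp(IntegerMatrix levels, IntegerVector cards, List parents,
                      int lstep, SEXP cache_ptr) {
  Data d = data_from_r(levels, cards);
  Cache* cache = cache_from_sexp(cache_ptr);
  Graph g = graph_from_list(parents, d.v);
  local_search(d, cache, g, lstep);
  return List::create(_["parents"] = graph_to_list(g),
                      _["score"] = graph_score(d, cache, g));
}

// One full colony iteration: `ants` constructions sharing the colony
// pheromone (with interleaved local updates), local search on the iteration
// best, colony-best bookkeeping, and the global pheromone update on the
// colony best. Stateless across calls: all colony state goes in and out.
// [[Rcpp::export]]
List colony_iterate_cpp(IntegerMatrix levels, IntegerVector cards,
                        NumericMatrix mi, NumericMatrix tau,
                        List best_parents, double best_score, bool has_best,
                        List cfg_list, double colony_seed, int iteration,
                        SEXP cache_ptr) {
  Data d = data_from_r(levels, cards);
  Cfg cfg = cfg_from_list(cfg_list);
  Cache* cache = cache_from_sexp(cache_ptr);
  NumericMatrix tau_out = clone(tau);
  double* tauv = REAL(tau_out);

  Graph it_best(d.v);
  double it_best_score = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < cfg.ants; ++k) {
    Rng rng(mix2(mix2((uint64_t)colony_seed, (uint64_t)iteration),
                 (uint64_t)k));
    Graph g = construct_one(d, cache, REAL(mi), tauv, cfg, rng);
    const double s = graph_score(d, cache, g);
    if (s > it_best_score) { it_best_score = s; it_best = g; }
  }
  local_search(d, cache, it_best, cfg.lstep);
  it_best_score = graph_score(d, cache, it_best);

  Graph best = has_best ? graph_from_list(best_parents, d.v) : Graph(d.v);
  bool improved = !has_best || it_best_score > best_score;
  if (improved) { best = it_best; best_score = it_best_score; }

  // global pheromone update on the colony best G+
  double denom = std::fabs(best_score);
  bool degenerate = denom == 0.0;
  if (degenerate) denom = std::numeric_limits<double>::min();
  const double deposit = cfg.rho / denom;
  for (int c = 0; c < d.v; ++c)
    for (uint16_t u : best.pa[c]) {
      double& t = tauv[(size_t)c * d.v + u];  // column-major (u, c)
      t = (1.0 - cfg.rho) * t + deposit;
    }

  return List::create(_["tau"] = tau_out,
                      _["best_parents"] = graph_to_list(best),
                      _["best_score"] = best_score,
                      _["iter_score"] = it_best_score,
                      _["improved"] = improved,
                      _["degenerate_deposit"] = degenerate);
}
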