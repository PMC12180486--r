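#include <Rcpp.h>
#include <vector>
#include <queue>
#include <random>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Hierarchical navigable small world graph over cosine distance
// (1 - inner product; vectors are unit-normalized at ingest, enforced on the
// R side). Single-threaded, fully deterministic: level draws come from a
// seeded mt19937 with manually constructed uniforms, and every comparison
// breaks ties by a caller-supplied rank (lexicographic id order).

struct Cand {
  double dist;
  int tie;
  int node;
};
// min-first ordering on (dist, tie)
struct CandGreater {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.tie > b.tie;
  }
};
// max-first ordering on (dist, tie)
struct CandLess {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.tie < b.tie;
  }
};

typedef std::vector<std::vector<std::vector<int> > > Adjacency;

struct Graph {
  int n, dim;
  std::vector<double> data;  // row-major
  std::vector<int> level;
  std::vector<int> tie;
  Adjacency adj;  // adj[node][layer] -> neighbors
  int entry;

  double dist(int a, int b) const {
    const double *x = &data[(size_t)a * dim], *y = &data[(size_t)b * dim];
    double s = 0;
    for (int d = 0; d < dim; ++d) s += x[d] * y[d];
    return 1.0 - s;
  }
  double distq(const double *q, int b) const {
    const double *y = &data[(size_t)b * dim];
    double s = 0;
    for (int d = 0; d < dim; ++d) s += q[d] * y[d];
    return 1.0 - s;
  }
};

// best-first bounded search on one layer; returns candidates sorted by
// (dist, tie) ascending
static std::vector<Cand> search_layer(const Graph &g, const double *q,
                                      const std::vector<int> &eps, int ef,
                                      int layer, std::vector<char> &visited) {
  std::fill(visited.begin(), visited.end(), 0);
  std::priority_queue<Cand, std::vector<Cand>, CandGreater> cand;
  std::priority_queue<Cand, std::vector<Cand>, CandLess> res;
  for (int e : eps) {
    if (visited[e]) continue;
    visited[e] = 1;
    Cand c{g.distq(q, e), g.tie[e], e};
    cand.push(c);
    res.push(c);
    if ((int)res.size() > ef) res.pop();
  }
  while (!cand.empty()) {
    Cand c = cand.top();
    cand.pop();
    Cand worst = res.top();
    if (c.dist > worst.dist || (c.dist == worst.dist && c.tie > worst.tie)) {
      if ((int)res.size() >= ef) break;
    }
    const std::vector<int> &nb = g.adj[c.node][layer];
    for (int e : nb) {
      if (visited[e]) continue;
      visited[e] = 1;
      double d = g.distq(q, e);
      Cand w = res.top();
      if ((int)res.size() < ef || d < w.dist ||
          (d == w.dist && g.tie[e] < w.tie)) {
        Cand nc{d, g.tie[e], e};
        cand.push(nc);
        res.push(nc);
        if ((int)res.size() > ef) res.pop();
      }
    }
  }
  std::vector<Cand> out;
  out.reserve(res.size());
  while (!res.empty()) {
    out.push_back(res.top());
    res.pop();
  }
  std::reverse(out.begin(), out.end());
  return out;
}

// neighbor-selection heuristic: accept a candidate only if it is closer to
// the base point than to every already-accepted neighbor
static std::vector<int> select_heuristic(const Graph &g, int base,
                                         const std::vector<Cand> &cands,
                                         int M) {
  std::vector<int> sel;
  for (const Cand &c : cands) {
    if ((int)sel.size() >= M) break;
    if (c.node == base) continue;
    bool ok = true;
    for (int r : sel) {
      if (g.dist(c.node, r) < c.dist) { ok = false; break; }
    }
    if (ok) sel.push_back(c.node);
  }
  return sel;
}

static void link_nodes(Graph &g, int a, int b, int layer) {
  g.adj[a][layer].push_back(b);
  g.adj[b][layer].push_back(a);
}

// shrink node e's neighbor list at `layer` to at most Mmax using the
// selection heuristic; removed links are deleted from both endpoints so the
// graph stays symmetric
static void shrink(Graph &g, int e, int layer, int Mmax) {
  std::vector<int> &nb = g.adj[e][layer];
  if ((int)nb.size() <= Mmax) return;
  std::vector<Cand> cands;
  cands.reserve(nb.size());
  for (int x : nb) cands.push_back(Cand{g.dist(e, x), g.tie[x], x});
  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.tie < b.tie;
  });
  std::vector<int> keep = select_heuristic(g, e, cands, Mmax);
  std::vector<char> kept(g.n, 0);
  for (int x : keep) kept[x] = 1;
  for (int x : nb) {
    if (!kept[x]) {
      std::vector<int> &other = g.adj[x][layer];
      other.erase(std::remove(other.begin(), other.end(), e), other.end());
    }
  }
  nb = keep;
}

// [[Rcpp::export(name = ".hnsw_build_cpp")]]
List hnsw_build_cpp(NumericMatrix mat, IntegerVector tie, int M,
                    int ef_construction, int seed, double level_mult) {
  const int n = mat.nrow(), dim = mat.ncol();
  if (n < 1) stop("empty database");
  Graph g;
  g.n = n;
  g.dim = dim;
  g.data.resize((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) g.data[(size_t)i * dim + d] = mat(i, d);
  g.tie.assign(tie.begin(), tie.end());
  if (level_mult <= 0) level_mult = 1.0 / std::log((double)M);

  std::mt19937 gen((uint32_t)seed);
  g.level.resize(n);
  for (int i = 0; i < n; ++i) {
    double u = (gen() + 0.5) / 4294967296.0;  // deterministic uniform (0,1)
    g.level[i] = (int)std::floor(-std::log(u) * level_mult);
  }
  g.adj.resize(n);
  for (int i = 0; i < n; ++i) g.adj[i].resize(g.level[i] + 1);

  std::vector<char> visited(n, 0);
  g.entry = 0;
  for (int i = 1; i < n; ++i) {
    const double *q = &g.data[(size_t)i * dim];
    int L = g.level[g.entry], l = g.level[i];
    std::vector<int> ep(1, g.entry);
    for (int lc = L; lc > l; --lc) {
      std::vector<Cand> w = search_layer(g, q, ep, 1, lc, visited);
      ep.assign(1, w[0].node);
    }
    for (int lc = std::min(L, l); lc >= 0; --lc) {
      std::vector<Cand> w = search_layer(g, q, ep, ef_construction, lc, visited);
      std::vector<int> neigh = select_heuristic(g, i, w, M);
      for (int e : neigh) link_nodes(g, i, e, lc);
      int Mmax = (lc == 0) ? 2 * M : M;
      for (int e : neigh) shrink(g, e, lc, Mmax);
      shrink(g, i, lc, Mmax);
      ep.clear();
      for (const Cand &c : w) ep.push_back(c.node);
    }
    if (l > L) g.entry = i;
  }

  List adjout(n);
  for (int i = 0; i < n; ++i) {
    List layers(g.level[i] + 1);
    for (int lc = 0; lc <= g.level[i]; ++lc) {
      IntegerVector v(g.adj[i][lc].size());
      for (size_t j = 0; j < g.adj[i][lc].size(); ++j)
        v[j] = g.adj[i][lc][j] + 1;
      layers[lc] = v;
    }
    adjout[i] = layers;
  }
  IntegerVector lev(n);
  for (int i = 0; i < n; ++i) lev[i] = g.level[i];
  return List::create(_["levels"] = lev, _["entry"] = g.entry + 1,
                      _["adjacency"] = adjout,
                      _["level_mult"] = level_mult);
}

static Graph graph_from_r(NumericMatrix mat, IntegerVector tie,
                          IntegerVector levels, int entry, List adjacency) {
  const int n = mat.nrow(), dim = mat.ncol();
  Graph g;
  g.n = n;
  g.dim = dim;
  g.data.resize((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) g.data[(size_t)i * dim + d] = mat(i, d);
  g.tie.assign(tie.begin(), tie.end());
  g.level.assign(levels.begin(), levels.end());
  g.entry = entry - 1;
  g.adj.resize(n);
  for (int i = 0; i < n; ++i) {
    List layers = adjacency[i];
    g.adj[i].resize(layers.size());
    for (int lc = 0; lc < layers.size(); ++lc) {
      IntegerVector v = layers[lc];
      g.adj[i][lc].reserve(v.size());
      for (int j = 0; j < v.size(); ++j) g.adj[i][lc].push_back(v[j] - 1);
    }
  }
  return g;
}

// [[Rcpp::export(name = ".hnsw_search_cpp")]]
List hnsw_search_cpp(NumericMatrix mat, IntegerVector tie, IntegerVector levels,
                     int entry, List adjacency, NumericMatrix queries, int k,
                     int ef_search) {
  Graph g = graph_from_r(mat, tie, levels, entry, adjacency);
  const int nq = queries.nrow();
  const int kk = std::min(k, g.n);
  IntegerMatrix idx(nq, kk);
  NumericMatrix sim(nq, kk);
  std::vector<char> visited(g.n, 0);
  std::vector<double> q(g.dim);
  for (int iq = 0; iq < nq; ++iq) {
    for (int d = 0; d < g.dim; ++d) q[d] = queries(iq, d);
    int L = g.level[g.entry];
    std::vector<int> ep(1, g.entry);
    for (int lc = L; lc >= 1; --lc) {
      std::vector<Cand> w = search_layer(g, q.data(), ep, 1, lc, visited);
      ep.assign(1, w[0].node);
    }
    std::vector<Cand> w =
        search_layer(g, q.data(), ep, std::max(ef_search, kk), 0, visited);
    for (int j = 0; j < kk; ++j) {
      if (j < (int)w.size()) {
        idx(iq, j) = w[j].node + 1;
        sim(iq, j) = 1.0 - w[j].dist;
      } else {
        idx(iq, j) = NA_INTEGER;
        sim(iq, j) = NA_REAL;
      }
    }
  }
  return List::create(_["idx"] = idx, _["sim"] = sim);
}
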