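#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-neighbour offsets in the package's fixed code order:
// 1=E, 2=SE, 3=S, 4=SW, 5=W, 6=NW, 7=N, 8=NE (ties broken by this order).
static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

typedef std::pair<double, int> PDI;

// Priority-flood depression filling with an epsilon gradient.
// Seeds: every marine (non-land) cell at its own elevation and every land
// cell on the map edge. A raised cell sits eps above its spill neighbour,
// which both removes pits and resolves flats deterministically.
// [[Rcpp::export]]
NumericMatrix cpp_fill_pits(NumericMatrix elev, LogicalMatrix land,
                            double eps) {
  int nr = elev.nrow(), nc = elev.ncol(), n = nr * nc;
  NumericMatrix filled(nr, nc);
  std::vector<bool> closed(n, false);
  std::priority_queue<PDI, std::vector<PDI>, std::greater<PDI> > pq;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int id = r + c * nr;
      filled[id] = elev[id];
      // edge seeds: grid-boundary cells; in a degenerate 1-row (1-col)
      // grid only the line's two ends drain off-map
      bool row_edge = (nr > 1) && (r == 0 || r == nr - 1);
      bool col_edge = (nc > 1) && (c == 0 || c == nc - 1);
      bool seed = !land[id] || row_edge || col_edge ||
        (nr == 1 && nc == 1);
      if (seed) {
        closed[id] = true;
        pq.push(PDI(elev[id], id));
      }
    }
  }
  while (!pq.empty()) {
    PDI top = pq.top(); pq.pop();
    int id = top.second;
    int r = id % nr, c = id / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      int nb = rr + cc * nr;
      if (closed[nb] || !land[nb]) continue;
      closed[nb] = true;
      filled[nb] = std::max(elev[nb], filled[id] + eps);
      pq.push(PDI(filled[nb], nb));
    }
  }
  return filled;
}

// Exact least-cost travel time (minutes) from any source cell.
// Edge cost = mean friction of the two cells (min/km) * step length (km).
// [[Rcpp::export]]
NumericMatrix cpp_travel_time(NumericMatrix friction, LogicalMatrix sources,
                              double cell_km) {
  int nr = friction.nrow(), nc = friction.ncol(), n = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  NumericMatrix minutes(nr, nc);
  std::fill(minutes.begin(), minutes.end(), R_PosInf);
  std::priority_queue<PDI, std::vector<PDI>, std::greater<PDI> > pq;
  for (int id = 0; id < n; ++id) {
    if (sources[id]) { minutes[id] = 0.0; pq.push(PDI(0.0, id)); }
  }
  while (!pq.empty()) {
    PDI top = pq.top(); pq.pop();
    double d = top.first; int id = top.second;
    if (d > minutes[id]) continue;
    int r = id % nr, c = id / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      int nb = rr + cc * nr;
      double step = cell_km * ((DR[k] != 0 && DC[k] != 0) ? SQ2 : 1.0);
      double w = 0.5 * (friction[id] + friction[nb]) * step;
      if (d + w < minutes[nb]) {
        minutes[nb] = d + w;
        pq.push(PDI(d + w, nb));
      }
    }
  }
  return minutes;
}

// Population reachable within max_minutes of every cell, by truncated
// expansions from each populated cell (isotropic friction => symmetric).
// [[Rcpp::export]]
NumericMatrix cpp_population_within(NumericMatrix friction,
                                    NumericMatrix population,
                                    double max_minutes, double cell_km) {
  int nr = friction.nrow(), nc = friction.ncol(), n = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  NumericMatrix out(nr, nc);
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> stamp(n, -1);
  std::priority_queue<PDI, std::vector<PDI>, std::greater<PDI> > pq;
  for (int src = 0; src < n; ++src) {
    double pop = population[src];
    if (!(pop > 0)) continue;
    // truncated Dijkstra from src, visit id = src
    dist[src] = 0.0; stamp[src] = src;
    pq.push(PDI(0.0, src));
    while (!pq.empty()) {
      PDI top = pq.top(); pq.pop();
      double d = top.first; int id = top.second;
      if (stamp[id] != src || d > dist[id]) continue;
      out[id] += pop;
      int r = id % nr, c = id / nr;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int nb = rr + cc * nr;
        double step = cell_km * ((DR[k] != 0 && DC[k] != 0) ? SQ2 : 1.0);
        double w = 0.5 * (friction[id] + friction[nb]) * step;
        double nd = d + w;
        if (nd > max_minutes) continue;
        if (stamp[nb] != src || nd < dist[nb]) {
          stamp[nb] = src; dist[nb] = nd;
          pq.push(PDI(nd, nb));
        }
      }
    }
  }
  return out;
}

static inline int popcount32(unsigned int x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// Lexicographic comparison of two equal-cardinality cell sets encoded as
// bitmasks (bit j = cell j+1): the set holding the lowest differing index
// is the smaller one.
static bool lex_smaller(unsigned int a, unsigned int b, int n) {
  for (int j = 0; j < n; ++j) {
    bool ja = (a >> j) & 1u, jb = (b >> j) & 1u;
    if (ja != jb) return ja;
  }
  return false;
}

// Exhaustive minimum-cardinality multicover: choose the fewest columns of v
// (m constraints x n cells) whose row sums meet `need`, ties broken by the
// lexicographically smallest cell-index set. n <= 20 enforced by the caller.
// [[Rcpp::export]]
IntegerVector cpp_cover_enumerate(NumericMatrix v, NumericVector need) {
  int m = v.nrow(), n = v.ncol();
  if (n > 20) stop("enumeration limited to 20 cells");
  unsigned int full = (n == 0) ? 0u : ((1u << n) - 1u);
  std::vector<double> tol(m);
  for (int i = 0; i < m; ++i) tol[i] = 1e-9 * std::max(1.0, need[i]);
  // subset-sum DP over masks
  std::vector<double> sums((size_t)(full + 1) * m, 0.0);
  int best_k = -1; unsigned int best_mask = 0u;
  // mask 0
  {
    bool ok = true;
    for (int i = 0; i < m; ++i) if (need[i] > tol[i]) { ok = false; break; }
    if (ok) { best_k = 0; best_mask = 0u; }
  }
  for (unsigned int mask = 1; mask <= full && full > 0; ++mask) {
    unsigned int low = mask & (~mask + 1u);
    unsigned int prev = mask ^ low;
    int j = 0; while (!((low >> j) & 1u)) ++j;
    double *s = &sums[(size_t)mask * m];
    const double *p = &sums[(size_t)prev * m];
    bool ok = true;
    for (int i = 0; i < m; ++i) {
      s[i] = p[i] + v(i, j);
      if (s[i] < need[i] - tol[i]) ok = false;
    }
    if (!ok) continue;
    int k = popcount32(mask);
    if (best_k < 0 || k < best_k ||
        (k == best_k && lex_smaller(mask, best_mask, n))) {
      best_k = k; best_mask = mask;
    }
    if (mask == full) break;
  }
  if (best_k < 0) stop("infeasible cover instance");
  IntegerVector sel(best_k);
  int pos = 0;
  for (int j = 0; j < n; ++j)
    if ((best_mask >> j) & 1u) sel[pos++] = j + 1;
  return sel;
}

struct BnB {
  int m, n;
  const NumericMatrix *v;
  std::vector<double> need, tol;
  std::vector<int> order;                 // cells, best-first
  std::vector<std::vector<double> > pref; // per constraint: prefix sums of
                                          // sorted-descending values
  int best_k;
  std::vector<int> best_sel, cur_sel;

  // admissible lower bound on extra cells needed for remaining deficits
  int bound(const std::vector<double> &def) const {
    int b = 0;
    for (int i = 0; i < m; ++i) {
      if (def[i] <= tol[i]) continue;
      const std::vector<double> &pf = pref[i];
      // smallest k with pf[k] >= deficit (pf[0]=0)
      int lo = 1, hi = (int)pf.size() - 1, k = -1;
      if (pf[hi] < def[i] - tol[i]) return n + 1; // infeasible remainder
      while (lo <= hi) {
        int mid = (lo + hi) / 2;
        if (pf[mid] >= def[i] - tol[i]) { k = mid; hi = mid - 1; }
        else lo = mid + 1;
      }
      if (k > b) b = k;
    }
    return b;
  }

  void dfs(int depth, std::vector<double> &def) {
    bool met = true;
    for (int i = 0; i < m; ++i) if (def[i] > tol[i]) { met = false; break; }
    if (met) {
      if ((int)cur_sel.size() < best_k) {
        best_k = (int)cur_sel.size();
        best_sel = cur_sel;
      }
      return;
    }
    if (depth >= n) return;
    if ((int)cur_sel.size() + bound(def) >= best_k) return;
    int j = order[depth];
    // include j
    std::vector<double> nd(def);
    for (int i = 0; i < m; ++i) nd[i] = std::max(0.0, def[i] - (*v)(i, j));
    cur_sel.push_back(j);
    dfs(depth + 1, nd);
    cur_sel.pop_back();
    // exclude j
    dfs(depth + 1, def);
  }
};

// Branch-and-bound minimum-cardinality multicover for moderate instance
// sizes; `init_sel` (1-based) supplies a feasible incumbent (e.g. greedy).
// [[Rcpp::export]]
IntegerVector cpp_cover_bnb(NumericMatrix v, NumericVector need,
                            IntegerVector init_sel) {
  BnB b;
  b.m = v.nrow(); b.n = v.ncol(); b.v = &v;
  b.need.assign(need.begin(), need.end());
  b.tol.resize(b.m);
  for (int i = 0; i < b.m; ++i) b.tol[i] = 1e-9 * std::max(1.0, b.need[i]);
  // order cells by total need-normalised value, descending; stable ties
  std::vector<double> score(b.n, 0.0);
  for (int j = 0; j < b.n; ++j)
    for (int i = 0; i < b.m; ++i)
      if (need[i] > 0) score[j] += v(i, j) / need[i];
  b.order.resize(b.n);
  for (int j = 0; j < b.n; ++j) b.order[j] = j;
  std::stable_sort(b.order.begin(), b.order.end(),
                   [&](int a, int c) { return score[a] > score[c]; });
  b.pref.assign(b.m, std::vector<double>());
  for (int i = 0; i < b.m; ++i) {
    std::vector<double> vals(b.n);
    for (int j = 0; j < b.n; ++j) vals[j] = v(i, j);
    std::sort(vals.begin(), vals.end(), std::greater<double>());
    b.pref[i].resize(b.n + 1, 0.0);
    for (int j = 0; j < b.n; ++j) b.pref[i][j + 1] = b.pref[i][j] + vals[j];
  }
  b.best_k = b.n + 1;
  b.best_sel.clear();
  if (init_sel.size() > 0) {
    b.best_k = init_sel.size();
    b.best_sel.resize(init_sel.size());
    for (int j = 0; j < init_sel.size(); ++j) b.best_sel[j] = init_sel[j] - 1;
  } else {
    // all cells always feasible for need <= column-sum totals
    b.best_k = b.n;
    b.best_sel.resize(b.n);
    for (int j = 0; j < b.n; ++j) b.best_sel[j] = j;
  }
  std::vector<double> def(b.need);
  b.dfs(0, def);
  IntegerVector out(b.best_sel.size());
  std::vector<int> sorted(b.best_sel);
  std::sort(sorted.begin(), sorted.end());
  for (size_t j = 0; j < sorted.size(); ++j) out[j] = sorted[j] + 1;
  return out;
}
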