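#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Depth-first branch-and-bound search for the minimum-weight colorful,
// location-monotone simple path of exactly l nodes from s to t.
//
// Pruning: once the partial path is deeper than the pre-traverse depth d,
// a branch is cut when f = g + w_min * (l - depth) exceeds the bound
// (h = w_min * remaining-steps is admissible: no edge weighs less than
// w_min, so f never overestimates the weight of any completion).
// Ties in weight resolve to the lexicographically smallest node sequence;
// neighbours are therefore visited in ascending index order, with node
// indices assigned in lexicographic name order by the R wrapper.

namespace {

const double EPS = 1e-9;

struct Ctx {
  std::vector<std::vector<int> > adj;
  std::vector<std::vector<double> > wt;
  const int *color;
  const int *loc;          // NA_INTEGER = wildcard compartment
  int l, d, t;
  bool enforce_loc;
  double wmin, bound;
  double best_w;
  std::vector<int> best_path;
  std::vector<int> path;
  std::vector<char> visited;
  std::vector<char> color_used;
  long long expanded;
};

void dfs(Ctx &c, int v, double g, int cur_rank) {
  int depth = (int)c.path.size();
  if (depth == c.l) {
    if (v == c.t) {
      if (g < c.best_w - EPS ||
          (std::abs(g - c.best_w) <= EPS &&
           (c.best_path.empty() || c.path < c.best_path))) {
        c.best_w = std::min(g, c.best_w);
        c.best_path = c.path;
      }
    }
    return;
  }
  const std::vector<int> &nb = c.adj[v];
  const std::vector<double> &wv = c.wt[v];
  for (size_t i = 0; i < nb.size(); ++i) {
    int u = nb[i];
    if (c.visited[u]) continue;
    int cu = c.color[u];
    if (c.color_used[cu]) continue;
    int newdepth = depth + 1;
    // t may only ever be the final node of the path
    if (u == c.t) {
      if (newdepth != c.l) continue;
    } else if (newdepth == c.l) {
      continue;
    }
    int new_rank = cur_rank;
    if (c.enforce_loc) {
      int lr = c.loc[u];
      if (lr != NA_INTEGER) {
        if (lr < cur_rank) continue;
        new_rank = lr;
      }
    }
    double gnew = g + wv[i];
    if (newdepth > c.d) {
      double lim = std::min(c.bound, c.best_w);
      double f = gnew + c.wmin * (c.l - newdepth);
      if (f > lim + EPS) continue;
    }
    c.visited[u] = 1;
    c.color_used[cu] = 1;
    c.path.push_back(u);
    c.expanded++;
    dfs(c, u, gnew, new_rank);
    c.path.pop_back();
    c.color_used[cu] = 0;
    c.visited[u] = 0;
  }
}

void fill_adj(Ctx &c, List adj, List wts) {
  int n = adj.size();
  c.adj.resize(n);
  c.wt.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = adj[i];
    NumericVector wi = wts[i];
    c.adj[i].assign(ai.begin(), ai.end());
    for (size_t j = 0; j < c.adj[i].size(); ++j) c.adj[i][j]--;  // to 0-based
    c.wt[i].assign(wi.begin(), wi.end());
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_astar(List adj, List wts, IntegerVector color, IntegerVector loc,
               int s, int t, int l, int d, double bound, double wmin,
               bool enforce_loc) {
  Ctx c;
  fill_adj(c, adj, wts);
  int n = (int)c.adj.size();
  int kmax = 0;
  for (int i = 0; i < n; ++i) kmax = std::max(kmax, color[i]);
  c.color = INTEGER(color);
  c.loc = INTEGER(loc);
  c.l = l;
  c.d = d;
  c.t = t - 1;
  c.enforce_loc = enforce_loc;
  c.wmin = wmin;
  c.bound = bound;
  c.best_w = R_PosInf;
  c.visited.assign(n, 0);
  c.color_used.assign(kmax + 1, 0);
  c.expanded = 0;

  int s0 = s - 1;
  c.visited[s0] = 1;
  c.color_used[color[s0]] = 1;
  c.path.push_back(s0);
  int r0 = INT_MIN;
  if (enforce_loc && loc[s0] != NA_INTEGER) r0 = loc[s0];
  dfs(c, s0, 0.0, r0);

  if (c.best_path.empty())
    return List::create(_["found"] = false,
                        _["expanded"] = (double)c.expanded);
  IntegerVector out(c.best_path.size());
  for (size_t i = 0; i < c.best_path.size(); ++i) out[i] = c.best_path[i] + 1;
  return List::create(_["found"] = true, _["path"] = out,
                      _["weight"] = c.best_w,
                      _["expanded"] = (double)c.expanded);
}

// Exact existence check for a colorful simple path of l nodes from s to t
// under a fixed coloring, by dynamic programming over color subsets
// (O(2^k * m * l)); used for success-rate experiments where only
// existence, not the minimum weight, matters.

// [[Rcpp::export]]
bool cpp_colorful_exists(List adj, IntegerVector color, int s, int t, int l,
                         int k) {
  int n = adj.size();
  std::vector<std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = adj[i];
    A[i].assign(ai.begin(), ai.end());
    for (size_t j = 0; j < A[i].size(); ++j) A[i][j]--;
  }
  int s0 = s - 1, t0 = t - 1;
  if (l == 1) return s0 == t0;
  size_t nmask = (size_t)1 << k;
  std::vector<char> cur(n * nmask, 0), nxt;
  cur[(size_t)s0 * nmask + ((size_t)1 << (color[s0] - 1))] = 1;
  for (int step = 2; step <= l; ++step) {
    nxt.assign(n * nmask, 0);
    bool any = false;
    for (int u = 0; u < n; ++u) {
      const char *row = &cur[(size_t)u * nmask];
      for (size_t m = 0; m < nmask; ++m) {
        if (!row[m]) continue;
        for (size_t j = 0; j < A[u].size(); ++j) {
          int v = A[u][j];
          size_t cb = (size_t)1 << (color[v] - 1);
          if (m & cb) continue;
          nxt[(size_t)v * nmask + (m | cb)] = 1;
          any = true;
        }
      }
    }
    cur.swap(nxt);
    if (!any) return false;
  }
  const char *rt = &cur[(size_t)t0 * nmask];
  for (size_t m = 0; m < nmask; ++m)
    if (rt[m]) return true;
  return false;
}
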