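// Exact solver for the discrete transportation problem
//
//   min sum_ij C(i,j) * pi(i,j)   s.t.  pi 1 = a,  pi' 1 = b,  pi >= 0,
//
// by the transportation (network) simplex on the bipartite spanning-tree
// basis.  Engineering choices for the n >> k regime this package meets
// (many observations, few atoms):
//
//  * north-west-corner starting basis (the R wrapper presorts rows and
//    columns along the dominant atom direction, which makes this start
//    near-optimal for near-one-dimensional geometry);
//  * a tiny multiplicative perturbation of the supplies breaks the massive
//    degeneracy of uniform marginals (relative size 1e-10, far below the
//    1e-8 marginal tolerance documented for transport plans);
//  * candidate-list pricing: a full O(nk) sweep gathers a list of the most
//    violated arcs, then cheap minor pivots consume the list, re-pricing
//    each candidate against the current duals;
//  * Bland's rule fallback after a long run of degenerate pivots keeps the
//    method finitely terminating even in pathological tie structures.
//
// The returned plan is a vertex of the transport polytope (at most n+k-1
// nonzeros) and the duals (u, v) certify optimality:
// c_ij - u_i - v_j >= -tol with equality-complementarity on the support.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Arc {
  int row;
  int col;
  double flow;
  bool active;
};

}  // namespace

// [[Rcpp::export]]
List transport_simplex_cpp(NumericMatrix cost, NumericVector supply,
                           NumericVector demand, bool perturb = true) {
  const int n = cost.nrow(), k = cost.ncol(), N = n + k;
  if (supply.size() != n || demand.size() != k)
    stop("marginal lengths do not match the cost matrix");

  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  double sa = 0, sb = 0;
  for (double x : a) { if (x < 0) stop("negative supply"); sa += x; }
  for (double x : b) { if (x < 0) stop("negative demand"); sb += x; }
  if (sa <= 0 || sb <= 0) stop("zero total mass");
  if (std::fabs(sa - sb) > 1e-8 * std::max(sa, sb))
    stop("unbalanced marginals");

  // anti-degeneracy perturbation, absorbed by the last demand
  if (perturb) {
    double extra = 0;
    for (int i = 0; i < n; ++i) {
      double d = a[i] * 1e-10 * (double)(i + 1) / (double)n;
      a[i] += d; extra += d;
    }
    b[k - 1] += extra;
    sb += extra; sa += extra;
  }
  { // exact balance up to roundoff
    const double scale = sa / sb;
    for (double &x : b) x *= scale;
  }

  double cmax = 0;
  for (int i = 0; i < n * k; ++i)
    cmax = std::max(cmax, std::fabs(cost[i]));
  const double opt_tol = 1e-11 * (1.0 + cmax);

  std::vector<Arc> arcs;
  arcs.reserve(2 * N);
  std::vector<std::vector<int>> adj(N);   // node -> incident basic arcs

  auto add_arc = [&](int i, int j, double f) {
    int id = (int)arcs.size();
    arcs.push_back({i, j, f, true});
    adj[i].push_back(id);
    adj[n + j].push_back(id);
    return id;
  };

  // ---- north-west corner starting basis (exactly n+k-1 arcs) ----
  {
    int i = 0, j = 0;
    double ra = a[0], rb = b[0];
    while (true) {
      double f = std::min(ra, rb);
      add_arc(i, j, f);
      ra -= f; rb -= f;
      if (i == n - 1 && j == k - 1) break;
      if ((ra <= rb && i < n - 1) || j == k - 1) {
        ++i; ra = a[i];
      } else {
        ++j; rb = b[j];
      }
    }
  }

  std::vector<double> u(n), v(k);
  std::vector<int> parent_node(N), parent_arc(N), order(N);
  std::vector<char> seen(N);

  auto compute_duals = [&]() {
    std::fill(seen.begin(), seen.end(), 0);
    int head = 0, tail = 0;
    order[tail++] = 0; seen[0] = 1; u[0] = 0.0;
    while (head < tail) {
      int node = order[head++];
      for (int id : adj[node]) {
        const Arc &e = arcs[id];
        int other = (node == e.row) ? n + e.col : e.row;
        if (seen[other]) continue;
        seen[other] = 1;
        if (other >= n) v[other - n] = cost(e.row, e.col) - u[e.row];
        else u[other] = cost(e.row, e.col) - v[node - n];
        order[tail++] = other;
      }
    }
    if (tail != N) stop("basis lost tree structure");
  };

  // pivot on entering arc (ei, ej); returns step length theta
  auto pivot = [&](int ei, int ej, bool bland) {
    std::fill(seen.begin(), seen.end(), 0);
    int head = 0, tail = 0;
    order[tail++] = ei; seen[ei] = 1;
    while (head < tail && !seen[n + ej]) {
      int node = order[head++];
      for (int id : adj[node]) {
        const Arc &e = arcs[id];
        int other = (node == e.row) ? n + e.col : e.row;
        if (seen[other]) continue;
        seen[other] = 1;
        parent_node[other] = node;
        parent_arc[other] = id;
        order[tail++] = other;
      }
    }
    std::vector<int> path;
    for (int node = n + ej; node != ei; node = parent_node[node])
      path.push_back(parent_arc[node]);
    // the arc adjacent to node ei (last in path) takes -theta; signs
    // alternate from there, and the bipartite path has odd length, so the
    // arc at the entering column also takes -theta
    double theta = R_PosInf;
    int leave = -1;
    {
      int sgn = -1;
      for (int t = (int)path.size() - 1; t >= 0; --t) {
        if (sgn < 0) {
          const Arc &e = arcs[path[t]];
          if (e.flow < theta - 1e-18 ||
              (leave >= 0 && std::fabs(e.flow - theta) <= 1e-18 && bland &&
               path[t] < leave)) {
            theta = e.flow; leave = path[t];
          }
        }
        sgn = -sgn;
      }
    }
    if (leave < 0) stop("no leaving arc found");
    {
      int sgn = -1;
      for (int t = (int)path.size() - 1; t >= 0; --t) {
        arcs[path[t]].flow += sgn * theta;
        if (arcs[path[t]].flow < 0) arcs[path[t]].flow = 0;  // roundoff
        sgn = -sgn;
      }
    }
    add_arc(ei, ej, theta);
    const Arc le = arcs[leave];
    arcs[leave].active = false;
    for (int node : {le.row, n + le.col}) {
      auto &lst = adj[node];
      for (size_t t = 0; t < lst.size(); ++t)
        if (lst[t] == leave) { lst[t] = lst.back(); lst.pop_back(); break; }
    }
    return theta;
  };

  const int list_cap = 64;
  const long max_pivots = 400L * N + 100000L;
  long pivots = 0;
  int degen_run = 0;
  bool bland = false;
  int status = 1;
  std::vector<std::pair<double, int>> cand;  // (reduced cost, arc j*n+i)
  cand.reserve(list_cap + 1);

  while (pivots <= max_pivots) {
    compute_duals();
    // ---- major sweep: gather the most violated arcs ----
    cand.clear();
    if (!bland) {
      for (int j = 0; j < k; ++j) {
        const double vj = v[j];
        for (int i = 0; i < n; ++i) {
          const double rc = cost(i, j) - u[i] - vj;
          if (rc < -opt_tol) {
            if ((int)cand.size() < list_cap) {
              cand.emplace_back(rc, j * n + i);
              if ((int)cand.size() == list_cap)
                std::make_heap(cand.begin(), cand.end());  // max-heap on rc
            } else if (rc < cand.front().first) {
              std::pop_heap(cand.begin(), cand.end());
              cand.back() = {rc, j * n + i};
              std::push_heap(cand.begin(), cand.end());
            }
          }
        }
      }
    } else {
      for (int j = 0; j < k && cand.empty(); ++j)
        for (int i = 0; i < n; ++i)
          if (cost(i, j) - u[i] - v[j] < -opt_tol) {
            cand.emplace_back(0.0, j * n + i);
            break;
          }
    }
    if (cand.empty()) { status = 0; break; }   // optimal

    // ---- minor pivots: consume the candidate list, re-pricing as duals
    // change; one dual recomputation per pivot ----
    bool first = true;
    while (pivots <= max_pivots) {
      if (!first) compute_duals();
      first = false;
      int best_arc = -1;
      double best_rc = -opt_tol;
      for (const auto &ca : cand) {
        const int i = ca.second % n, j = ca.second / n;
        const double rc = cost(i, j) - u[i] - v[j];
        if (rc < best_rc) { best_rc = rc; best_arc = ca.second; }
      }
      if (best_arc < 0) break;
      const double theta = pivot(best_arc % n, best_arc / n, bland);
      ++pivots;
      if (theta <= 0) {
        if (++degen_run > 200) bland = true;
      } else {
        degen_run = 0;
        bland = false;
      }
    }
  }

  NumericMatrix plan(n, k);
  for (const Arc &e : arcs)
    if (e.active && e.flow != 0) plan(e.row, e.col) += e.flow;

  return List::create(_["plan"] = plan,
                      _["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["status"] = status,
                      _["pivots"] = (double)pivots);
}
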