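#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coordinate-descent relocation of movable vertices to the weighted geometric
// median of their neighbours. Minimizes sum_e w_e * |x_u - x_v| over the
// positions of the movable vertices; with w_e = alpha + (1 - alpha) * (tips
// routed through e) this equals the joint cost/travel objective, so each
// relocation step is an exact coordinate-descent step for that objective.
//
// An iterate that coincides with a neighbour uses the Vardi-Zhang update: it
// stays put when the pull from the remaining neighbours does not exceed the
// coincident edge weight (subgradient optimality at the vertex), otherwise it
// escapes along the pull direction. This is what makes degenerate junctions
// (e.g. a star centre that should stay at the root for small alpha) behave
// correctly instead of being trapped by a 0/0 Weiszfeld step.
//
// [[Rcpp::export]]
List weiszfeld_descent(NumericMatrix coords, IntegerMatrix edges,
                       NumericVector weights, LogicalVector movable,
                       double tol, int max_sweeps) {
  const int nv = coords.nrow(), ne = edges.nrow();
  std::vector< std::vector<int> > adj(nv);
  std::vector< std::vector<double> > wadj(nv);
  for (int e = 0; e < ne; ++e) {
    const int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);  wadj[a].push_back(weights[e]);
    adj[b].push_back(a);  wadj[b].push_back(weights[e]);
  }
  NumericMatrix x = clone(coords);
  const double eps = 1e-12;
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double maxmove = 0.0;
    for (int v = 0; v < nv; ++v) {
      if (!movable[v] || adj[v].empty()) continue;
      double sx = 0, sy = 0, sw = 0, rx = 0, ry = 0, wnear = 0;
      for (size_t k = 0; k < adj[v].size(); ++k) {
        const int u = adj[v][k];
        const double w = wadj[v][k];
        const double dx = x(u, 0) - x(v, 0), dy = x(u, 1) - x(v, 1);
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < eps) { wnear += w; continue; }
        sx += w * x(u, 0) / d;  sy += w * x(u, 1) / d;  sw += w / d;
        rx += w * dx / d;       ry += w * dy / d;
      }
      if (sw <= 0) continue;  // all neighbours coincide with v
      const double tx = sx / sw, ty = sy / sw;
      double nx, ny;
      if (wnear > 0) {
        const double rn = std::sqrt(rx * rx + ry * ry);
        if (rn <= wnear) continue;  // optimal at the coincident point
        const double beta = 1.0 - wnear / rn;
        nx = beta * tx + (1.0 - beta) * x(v, 0);
        ny = beta * ty + (1.0 - beta) * x(v, 1);
      } else {
        nx = tx;  ny = ty;
      }
      const double mv = std::max(std::fabs(nx - x(v, 0)),
                                 std::fabs(ny - x(v, 1)));
      if (mv > maxmove) maxmove = mv;
      x(v, 0) = nx;  x(v, 1) = ny;
    }
    if (maxmove < tol) { ++sweep; break; }
  }
  double obj = 0.0;
  for (int e = 0; e < ne; ++e) {
    const double dx = x(edges(e, 0), 0) - x(edges(e, 1), 0);
    const double dy = x(edges(e, 0), 1) - x(edges(e, 1), 1);
    obj += weights[e] * std::sqrt(dx * dx + dy * dy);
  }
  return List::create(_["coords"] = x, _["objective"] = obj,
                      _["sweeps"] = sweep);
}

// Weighted total edge length of a fixed topology — the joint objective for
// given junction coordinates. Hot path of the brute-force polish.
// [[Rcpp::export]]
double edge_weighted_length(NumericMatrix coords, IntegerMatrix edges,
                            NumericVector weights) {
  double obj = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    const double dx = coords(edges(e, 0), 0) - coords(edges(e, 1), 0);
    const double dy = coords(edges(e, 0), 1) - coords(edges(e, 1), 1);
    obj += weights[e] * std::sqrt(dx * dx + dy * dy);
  }
  return obj;
}
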