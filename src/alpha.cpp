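#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Alpha-shape boundary of a planar point set, returned as the ordered outer
// loop (1-based indices into the input, counter-clockwise).
//
// An edge (p,q) with |pq| <= 2*alpha lies on the alpha boundary iff at least
// one of the two radius-alpha disks through p and q contains no other point.
// Candidate pairs and emptiness checks use a uniform grid of cell size alpha.

namespace {

struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int> > bins;

  Grid(const double *x, const double *y, int n, double cell_) : cell(cell_) {
    x0 = y0 = std::numeric_limits<double>::infinity();
    double x1 = -x0, y1 = -y0;
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, x[i]); x1 = std::max(x1, x[i]);
      y0 = std::min(y0, y[i]); y1 = std::max(y1, y[i]);
    }
    nx = std::max(1, (int)std::floor((x1 - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / cell) + 1);
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < n; ++i) bins[bin(x[i], y[i])].push_back(i);
  }
  size_t bin(double px, double py) const {
    int ix = std::min(nx - 1, std::max(0, (int)std::floor((px - x0) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)std::floor((py - y0) / cell)));
    return (size_t)ix + (size_t)nx * iy;
  }
  template <class F>
  void around(double px, double py, int ring, F f) const {
    int ix = (int)std::floor((px - x0) / cell);
    int iy = (int)std::floor((py - y0) / cell);
    for (int dy = -ring; dy <= ring; ++dy) {
      int jy = iy + dy;
      if (jy < 0 || jy >= ny) continue;
      for (int dx = -ring; dx <= ring; ++dx) {
        int jx = ix + dx;
        if (jx < 0 || jx >= nx) continue;
        const std::vector<int> &b = bins[(size_t)jx + (size_t)nx * jy];
        for (size_t t = 0; t < b.size(); ++t) f(b[t]);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_alpha_outline(NumericMatrix xy, double alpha) {
  int n = xy.nrow();
  if (n < 3) stop("need at least 3 points");
  if (alpha <= 0) stop("alpha must be positive");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = xy(i, 0); y[i] = xy(i, 1); }
  Grid grid(x.data(), y.data(), n, alpha);

  const double tol = 1e-9 * alpha;
  std::vector<std::pair<int, int> > edges;
  std::vector<int> cand;

  for (int i = 0; i < n; ++i) {
    cand.clear();
    grid.around(x[i], y[i], 2, [&](int j) {
      if (j > i) cand.push_back(j);
    });
    for (size_t t = 0; t < cand.size(); ++t) {
      int j = cand[t];
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > 4 * alpha * alpha || d2 == 0) continue;
      double d = std::sqrt(d2);
      double h = std::sqrt(std::max(0.0, alpha * alpha - d2 / 4));
      double mx = (x[i] + x[j]) / 2, my = (y[i] + y[j]) / 2;
      double ux = -dy / d, uy = dx / d;  // unit perpendicular
      for (int side = 0; side < 2; ++side) {
        double cx = mx + (side ? -h : h) * ux;
        double cy = my + (side ? -h : h) * uy;
        bool empty = true;
        grid.around(cx, cy, 2, [&](int k2) {
          if (!empty || k2 == i || k2 == j) return;
          double ex = x[k2] - cx, ey = y[k2] - cy;
          if (ex * ex + ey * ey < (alpha - tol) * (alpha - tol)) empty = false;
        });
        if (empty) {
          edges.push_back(std::make_pair(i, j));
          break;
        }
      }
    }
  }
  if (edges.empty())
    stop("no alpha-boundary edges found; increase alpha");

  // adjacency restricted to boundary edges
  std::unordered_map<int, std::vector<int> > adj;
  for (size_t e = 0; e < edges.size(); ++e) {
    adj[edges[e].first].push_back(edges[e].second);
    adj[edges[e].second].push_back(edges[e].first);
  }

  // start at lowest boundary vertex (guaranteed on the outer loop)
  int start = -1;
  for (std::unordered_map<int, std::vector<int> >::iterator it = adj.begin();
       it != adj.end(); ++it) {
    int v = it->first;
    if (start < 0 || y[v] < y[start] || (y[v] == y[start] && x[v] < x[start]))
      start = v;
  }

  // walk the outer loop counter-clockwise keeping the interior on the left:
  // from the incoming direction take the sharpest available left turn
  std::vector<int> loop;
  loop.push_back(start);
  int prev = -1, cur = start;
  double in_dx = 1.0, in_dy = 0.0;  // virtual incoming direction at start
  size_t max_steps = 2 * edges.size() + 2;
  for (size_t step = 0; step < max_steps; ++step) {
    const std::vector<int> &nbs = adj[cur];
    int best = -1;
    double best_ang = -10.0;
    for (size_t t = 0; t < nbs.size(); ++t) {
      int w = nbs[t];
      if (w == prev && nbs.size() > 1) continue;
      double ox = x[w] - x[cur], oy = y[w] - y[cur];
      double norm = std::sqrt(ox * ox + oy * oy);
      if (norm == 0) continue;
      ox /= norm; oy /= norm;
      // CCW angle from incoming direction to outgoing, in (-pi, pi]
      double ang = std::atan2(in_dx * oy - in_dy * ox,
                              in_dx * ox + in_dy * oy);
      if (ang > best_ang) { best_ang = ang; best = w; }
    }
    if (best < 0) stop("open alpha boundary; increase alpha");
    prev = cur;
    cur = best;
    if (cur == start) break;
    loop.push_back(cur);
    in_dx = x[cur] - x[prev];
    in_dy = y[cur] - y[prev];
    double nn = std::sqrt(in_dx * in_dx + in_dy * in_dy);
    in_dx /= nn; in_dy /= nn;
    if (step + 1 == max_steps)
      stop("alpha boundary walk did not close; increase alpha");
  }
  if (loop.size() < 3) stop("degenerate alpha boundary; increase alpha");

  // orient counter-clockwise (positive shoelace area)
  double area2 = 0.0;
  for (size_t t = 0; t < loop.size(); ++t) {
    size_t u = (t + 1) % loop.size();
    area2 += x[loop[t]] * y[loop[u]] - x[loop[u]] * y[loop[t]];
  }
  if (area2 < 0) std::reverse(loop.begin() + 1, loop.end());

  IntegerVector idx(loop.size());
  for (size_t t = 0; t < loop.size(); ++t) idx[t] = loop[t] + 1;
  return List::create(_["indices"] = idx, _["n_edges"] = (int)edges.size());
}

// Count query points strictly inside or on a simple polygon (even-odd rule).
// [[Rcpp::export]]
int cpp_count_in_polygon(NumericMatrix poly, NumericMatrix pts) {
  int nv = poly.nrow(), n = pts.nrow();
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    bool inside = false, boundary = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      double ax = poly(a, 0), ay = poly(a, 1);
      double bx = poly(b, 0), by = poly(b, 1);
      // on-segment test
      double cross = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
      double d2seg = (bx - ax) * (bx - ax) + (by - ay) * (by - ay);
      if (cross * cross <= 1e-24 * std::max(1.0, d2seg)) {
        double dot = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
        if (dot >= 0 && dot <= d2seg) { boundary = true; break; }
      }
      if ((ay > py) != (by > py)) {
        double xint = ax + (py - ay) / (by - ay) * (bx - ax);
        if (px < xint) inside = !inside;
      }
    }
    if (inside || boundary) ++cnt;
  }
  return cnt;
}

// Does any pair of non-adjacent closed-polygon edges properly intersect?
// [[Rcpp::export]]
bool cpp_polygon_self_intersects(NumericMatrix v) {
  int n = v.nrow();
  if (n < 4) return false;
  for (int i = 0; i < n - 1; ++i) {
    double ax = v(i, 0), ay = v(i, 1);
    double bx = v(i + 1, 0), by = v(i + 1, 1);
    int jmax = (i == 0) ? n - 1 : n;
    for (int j = i + 2; j < jmax; ++j) {
      int j2 = (j + 1) % n;
      double cx = v(j, 0), cy = v(j, 1);
      double dx = v(j2, 0), dy = v(j2, 1);
      double d1 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      double d2 = (bx - ax) * (dy - ay) - (by - ay) * (dx - ax);
      double d3 = (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx);
      double d4 = (dx - cx) * (by - cy) - (dy - cy) * (bx - cx);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return true;
    }
  }
  return false;
}
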