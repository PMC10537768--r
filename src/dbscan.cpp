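#include <Rcpp.h>
#include "kdtree.h"
using namespace Rcpp;

// Epsilon-neighbourhood of point `index` (1-based), inclusive of the point.
// [[Rcpp::export]]
IntegerVector cpp_region_query(NumericMatrix pts, int index, double eps) {
  int n = pts.nrow();
  if (index < 1 || index > n) stop("invalid point index");
  if (eps <= 0) stop("eps must be positive");
  KDTree3 tree(pts.begin(), n);
  std::vector<int> nb;
  double q[3] = {pts(index - 1, 0), pts(index - 1, 1), pts(index - 1, 2)};
  tree.radius(q, eps, nb);
  IntegerVector out(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) out[i] = nb[i] + 1;
  return out;
}

// Density clustering with noise, seeds scanned in point-index order.
// Cluster ids 1..K, noise 0. A point first marked noise can later join a
// cluster as a border point. Core flag: |eps-neighbourhood| >= min_pts.
// [[Rcpp::export]]
List cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  if (n < 1) stop("empty cloud");
  if (eps <= 0) stop("eps must be positive");
  if (min_pts < 1) stop("min_pts must be >= 1");
  KDTree3 tree(pts.begin(), n);

  std::vector<int> cluster(n, 0);
  std::vector<bool> labeled(n, false), core(n, false);
  std::vector<int> nb, nb2;

  int cl = 0;
  for (int p = 0; p < n; ++p) {
    if (labeled[p]) continue;
    labeled[p] = true;
    double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    tree.radius(q, eps, nb);
    if ((int)nb.size() < min_pts) continue;  // provisional noise
    core[p] = true;
    ++cl;
    cluster[p] = cl;
    std::vector<int> seeds(nb);
    for (size_t si = 0; si < seeds.size(); ++si) {
      int s = seeds[si];
      if (!labeled[s]) {
        labeled[s] = true;
        double qs[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
        tree.radius(qs, eps, nb2);
        if ((int)nb2.size() >= min_pts) {
          core[s] = true;
          seeds.insert(seeds.end(), nb2.begin(), nb2.end());
        }
      }
      if (cluster[s] == 0) cluster[s] = cl;
    }
  }

  IntegerVector cl_out(n);
  LogicalVector core_out(n);
  for (int i = 0; i < n; ++i) {
    cl_out[i] = cluster[i];
    core_out[i] = core[i];
  }
  return List::create(_["cluster_id"] = cl_out, _["core"] = core_out,
                      _["n_clusters"] = cl);
}
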