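#include <Rcpp.h>
#include "kdtree.h"
using namespace Rcpp;

// Mean distance from each point to its k nearest other points (self excluded).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points");
  KDTree3 tree(pts.begin(), n);
  NumericVector out(n);
  std::vector<std::pair<double, int> > heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    tree.knn(q, k, i, heap);
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(heap[j].first);
    out[i] = s / k;
  }
  return out;
}

// Distance from each query point to its nearest point in `ref` (no exclusion).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix ref, NumericMatrix query) {
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) stop("reference set is empty");
  KDTree3 tree(ref.begin(), n);
  NumericVector out(m);
  std::vector<std::pair<double, int> > heap;
  for (int i = 0; i < m; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    tree.knn(q, 1, -1, heap);
    out[i] = std::sqrt(heap[0].first);
  }
  return out;
}

// Nearest-neighbour spacing within one set (self excluded).
// [[Rcpp::export]]
NumericVector cpp_self_nn_dist(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 2) stop("need at least two points");
  KDTree3 tree(pts.begin(), n);
  NumericVector out(n);
  std::vector<std::pair<double, int> > heap;
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    tree.knn(q, 1, i, heap);
    out[i] = std::sqrt(heap[0].first);
  }
  return out;
}
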