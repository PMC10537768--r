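#ifndef PIGBACK_KDTREE_H
#define PIGBACK_KDTREE_H

#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

// Minimal 3D kd-tree over column-major coordinates (as R stores matrices).
// Neighbour ties at equal distance are broken by point index so results are
// stable under permutation of equidistant points.
class KDTree3 {
public:
  KDTree3(const double *pts, int n) : pts_(pts), n_(n) {
    idx_.resize(n_);
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    nodes_.reserve(2 * n_);
    root_ = build(0, n_);
  }

  // k nearest neighbours of query point q, optionally excluding index `self`.
  // Returns squared distances via out_d2 (sorted ascending, ties by index).
  void knn(const double *q, int k, int self,
           std::vector<std::pair<double, int> > &heap) const {
    heap.clear();
    search_knn(root_, q, k, self, heap);
    std::sort(heap.begin(), heap.end(), cmp_lt);
  }

  // all indices within radius eps of q (inclusive), ascending index order
  void radius(const double *q, double eps, std::vector<int> &out) const {
    out.clear();
    search_radius(root_, q, eps * eps, out);
    std::sort(out.begin(), out.end());
  }

private:
  struct Node {
    int point;
    int axis;
    int left, right;
  };

  const double *pts_;
  int n_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;
  int root_;

  double coord(int i, int ax) const { return pts_[i + (size_t)n_ * ax]; }

  double dist2(const double *q, int i) const {
    double dx = q[0] - coord(i, 0);
    double dy = q[1] - coord(i, 1);
    double dz = q[2] - coord(i, 2);
    return dx * dx + dy * dy + dz * dz;
  }

  static bool cmp_lt(const std::pair<double, int> &a,
                     const std::pair<double, int> &b) {
    if (a.first != b.first) return a.first < b.first;
    return a.second < b.second;
  }

  int build(int lo, int hi) {
    if (lo >= hi) return -1;
    // split along widest extent for balanced trees on anisotropic clouds
    double mn[3], mx[3];
    for (int ax = 0; ax < 3; ++ax) {
      mn[ax] = std::numeric_limits<double>::infinity();
      mx[ax] = -mn[ax];
    }
    for (int i = lo; i < hi; ++i)
      for (int ax = 0; ax < 3; ++ax) {
        double v = coord(idx_[i], ax);
        if (v < mn[ax]) mn[ax] = v;
        if (v > mx[ax]) mx[ax] = v;
      }
    int axis = 0;
    for (int ax = 1; ax < 3; ++ax)
      if (mx[ax] - mn[ax] > mx[axis] - mn[axis]) axis = ax;
    int mid = (lo + hi) / 2;
    const double *p = pts_;
    int n = n_;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [p, n, axis](int a, int b) {
                       double va = p[a + (size_t)n * axis];
                       double vb = p[b + (size_t)n * axis];
                       if (va != vb) return va < vb;
                       return a < b;
                     });
    Node nd;
    nd.point = idx_[mid];
    nd.axis = axis;
    int me = (int)nodes_.size();
    nodes_.push_back(nd);
    int l = build(lo, mid);
    int r = build(mid + 1, hi);
    nodes_[me].left = l;
    nodes_[me].right = r;
    return me;
  }

  // max-heap ordering: the "worst" (largest dist, then largest index) on top
  static bool cmp_heap(const std::pair<double, int> &a,
                       const std::pair<double, int> &b) {
    if (a.first != b.first) return a.first < b.first;
    return a.second < b.second;
  }

  void consider(const double *q, int i, int k, int self,
                std::vector<std::pair<double, int> > &heap) const {
    if (i == self) return;
    double d2 = dist2(q, i);
    std::pair<double, int> cand(d2, i);
    if ((int)heap.size() < k) {
      heap.push_back(cand);
      std::push_heap(heap.begin(), heap.end(), cmp_heap);
    } else if (cmp_lt(cand, heap.front())) {
      std::pop_heap(heap.begin(), heap.end(), cmp_heap);
      heap.back() = cand;
      std::push_heap(heap.begin(), heap.end(), cmp_heap);
    }
  }

  void search_knn(int node, const double *q, int k, int self,
                  std::vector<std::pair<double, int> > &heap) const {
    if (node < 0) return;
    const Node &nd = nodes_[node];
    consider(q, nd.point, k, self, heap);
    double delta = q[nd.axis] - coord(nd.point, nd.axis);
    int near = delta <= 0 ? nd.left : nd.right;
    int far = delta <= 0 ? nd.right : nd.left;
    search_knn(near, q, k, self, heap);
    if ((int)heap.size() < k || delta * delta <= heap.front().first)
      search_knn(far, q, k, self, heap);
  }

  void search_radius(int node, const double *q, double eps2,
                     std::vector<int> &out) const {
    if (node < 0) return;
    const Node &nd = nodes_[node];
    if (dist2(q, nd.point) <= eps2) out.push_back(nd.point);
    double delta = q[nd.axis] - coord(nd.point, nd.axis);
    int near = delta <= 0 ? nd.left : nd.right;
    int far = delta <= 0 ? nd.right : nd.left;
    search_radius(near, q, eps2, out);
    if (delta * delta <= eps2) search_radius(far, q, eps2, out);
  }
};

#endif
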