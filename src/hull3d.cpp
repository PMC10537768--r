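#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D convex hull by quickhull with outside sets. Returns triangular facets
// (outward-oriented), hull vertex indices, enclosed volume and surface area.

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
  return r;
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int v[3];
  int nb[3];        // neighbour across edge (v[i], v[(i+1)%3])
  Vec3 n;           // outward unit normal
  double off;       // plane offset: dot(n, x) = off
  std::vector<int> outside;
  bool alive;
};

struct Hull {
  const std::vector<Vec3> &P;
  std::vector<Face> faces;
  double eps;

  Hull(const std::vector<Vec3> &pts, double eps_) : P(pts), eps(eps_) {}

  double dist(int f, int p) const {
    return dot(faces[f].n, P[p]) - faces[f].off;
  }

  void set_plane(Face &f) {
    Vec3 nrm = cross(sub(P[f.v[1]], P[f.v[0]]), sub(P[f.v[2]], P[f.v[0]]));
    double ln = norm(nrm);
    if (ln > 0) { nrm.x /= ln; nrm.y /= ln; nrm.z /= ln; }
    f.n = nrm;
    f.off = dot(nrm, P[f.v[0]]);
  }

  int edge_index(const Face &f, int a, int b) const {
    for (int i = 0; i < 3; ++i)
      if (f.v[i] == a && f.v[(i + 1) % 3] == b) return i;
    return -1;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_hull3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i].x = pts(i, 0); P[i].y = pts(i, 1); P[i].z = pts(i, 2);
  }
  for (int ax = 0; ax < 3; ++ax) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = ax == 0 ? P[i].x : (ax == 1 ? P[i].y : P[i].z);
      lo = std::min(lo, v); hi = std::max(hi, v);
    }
    scale = std::max(scale, hi - lo);
  }
  if (scale <= 0) stop("degenerate cloud: all points coincide");
  double eps = 1e-10 * scale;

  // initial simplex: extreme pair, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  double best = -1.0;
  for (int ax = 0; ax < 3; ++ax) {
    int lo = 0, hi = 0;
    for (int i = 1; i < n; ++i) {
      double v = ax == 0 ? P[i].x : (ax == 1 ? P[i].y : P[i].z);
      double vl = ax == 0 ? P[lo].x : (ax == 1 ? P[lo].y : P[lo].z);
      double vh = ax == 0 ? P[hi].x : (ax == 1 ? P[hi].y : P[hi].z);
      if (v < vl) lo = i;
      if (v > vh) hi = i;
    }
    double d = norm(sub(P[hi], P[lo]));
    if (d > best) { best = d; i0 = lo; i1 = hi; }
  }
  if (best <= eps) stop("degenerate cloud: all points coincide");
  Vec3 dir = sub(P[i1], P[i0]);
  int i2 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0]))) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps) stop("degenerate cloud: points are collinear");
  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  double ln = norm(nrm);
  nrm.x /= ln; nrm.y /= ln; nrm.z /= ln;
  double off = dot(nrm, P[i0]);
  int i3 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, P[i]) - off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate cloud: points are coplanar");

  Hull H(P, eps);
  // orient tetrahedron so all faces point outward
  if (dot(nrm, P[i3]) - off > 0) std::swap(i1, i2);
  int tv[4] = {i0, i1, i2, i3};
  int fv[4][3] = {{0, 1, 2}, {0, 3, 1}, {1, 3, 2}, {2, 3, 0}};
  for (int f = 0; f < 4; ++f) {
    Face fc;
    for (int t = 0; t < 3; ++t) fc.v[t] = tv[fv[f][t]];
    fc.alive = true;
    H.set_plane(fc);
    H.faces.push_back(fc);
  }
  // adjacency among the 4 faces
  for (int f = 0; f < 4; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = H.faces[f].v[e], b = H.faces[f].v[(e + 1) % 3];
      for (int g = 0; g < 4; ++g) {
        if (g == f) continue;
        if (H.edge_index(H.faces[g], b, a) >= 0) H.faces[f].nb[e] = g;
      }
    }
  // assign outside sets
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (int f = 0; f < 4; ++f) {
      if (H.dist(f, i) > eps) { H.faces[f].outside.push_back(i); break; }
    }
  }

  std::vector<int> stack;
  for (int f = 0; f < 4; ++f)
    if (!H.faces[f].outside.empty()) stack.push_back(f);

  std::vector<int> visible, horizon_face, horizon_edge;
  while (!stack.empty()) {
    int f = stack.back();
    stack.pop_back();
    if (!H.faces[f].alive || H.faces[f].outside.empty()) continue;
    // farthest outside point
    int p = -1;
    double bd = -1.0;
    for (size_t t = 0; t < H.faces[f].outside.size(); ++t) {
      double d = H.dist(f, H.faces[f].outside[t]);
      if (d > bd) { bd = d; p = H.faces[f].outside[t]; }
    }
    // find visible faces by BFS
    visible.clear();
    horizon_face.clear();
    horizon_edge.clear();
    std::vector<int> bfs;
    bfs.push_back(f);
    std::unordered_map<int, bool> seen;
    seen[f] = true;
    while (!bfs.empty()) {
      int g = bfs.back();
      bfs.pop_back();
      visible.push_back(g);
      for (int e = 0; e < 3; ++e) {
        int h = H.faces[g].nb[e];
        if (H.dist(h, p) > eps) {
          if (!seen[h]) { seen[h] = true; bfs.push_back(h); }
        } else {
          horizon_face.push_back(g);
          horizon_edge.push_back(e);
        }
      }
    }
    // build the fan of new faces over the horizon
    std::vector<int> pool;  // points to redistribute
    for (size_t t = 0; t < visible.size(); ++t) {
      Face &vf = H.faces[visible[t]];
      vf.alive = false;
      pool.insert(pool.end(), vf.outside.begin(), vf.outside.end());
      vf.outside.clear();
    }
    std::unordered_map<long long, int> open_edge;  // (v from p side) -> face
    std::vector<int> fresh;
    for (size_t t = 0; t < horizon_face.size(); ++t) {
      int g = horizon_face[t], e = horizon_edge[t];
      int a = H.faces[g].v[e], b = H.faces[g].v[(e + 1) % 3];
      int out = H.faces[g].nb[e];  // surviving neighbour
      Face nf;
      nf.v[0] = a; nf.v[1] = b; nf.v[2] = p;
      nf.alive = true;
      H.set_plane(nf);
      int id = (int)H.faces.size();
      nf.nb[0] = out;
      nf.nb[1] = -1;  // edge (b, p), to be matched
      nf.nb[2] = -1;  // edge (p, a)
      H.faces.push_back(nf);
      fresh.push_back(id);
      // fix surviving neighbour's adjacency
      int ei = H.edge_index(H.faces[out], b, a);
      H.faces[out].nb[ei] = id;
      // match fan neighbours via shared horizon vertices
      long long kb = b;
      long long ka = a;
      std::unordered_map<long long, int>::iterator it = open_edge.find(kb);
      if (it == open_edge.end()) open_edge[kb] = id;
      else {
        int other = it->second;  // face whose (p, a'=b) edge matches our (b, p)
        H.faces[id].nb[1] = other;
        H.faces[other].nb[2] = id;
      }
      it = open_edge.find(ka);
      if (it == open_edge.end()) open_edge[ka] = id;
      else {
        int other = it->second;
        H.faces[id].nb[2] = other;
        H.faces[other].nb[1] = id;
      }
    }
    // redistribute points
    for (size_t t = 0; t < pool.size(); ++t) {
      int q = pool[t];
      if (q == p) continue;
      for (size_t u = 0; u < fresh.size(); ++u) {
        if (H.dist(fresh[u], q) > eps) {
          H.faces[fresh[u]].outside.push_back(q);
          break;
        }
      }
    }
    for (size_t u = 0; u < fresh.size(); ++u)
      if (!H.faces[fresh[u]].outside.empty()) stack.push_back(fresh[u]);
  }

  // gather alive faces; compute area and volume (divergence theorem)
  std::vector<int> alive;
  for (size_t f = 0; f < H.faces.size(); ++f)
    if (H.faces[f].alive) alive.push_back((int)f);
  double area = 0.0, vol6 = 0.0;
  Vec3 origin = P[i0];
  IntegerMatrix tri((int)alive.size(), 3);
  std::vector<bool> on_hull(n, false);
  for (size_t t = 0; t < alive.size(); ++t) {
    const Face &fc = H.faces[alive[t]];
    Vec3 a = sub(P[fc.v[0]], origin);
    Vec3 b = sub(P[fc.v[1]], origin);
    Vec3 c = sub(P[fc.v[2]], origin);
    area += 0.5 * norm(cross(sub(b, a), sub(c, a)));
    vol6 += dot(a, cross(b, c));
    for (int e = 0; e < 3; ++e) {
      tri(t, e) = fc.v[e] + 1;
      on_hull[fc.v[e]] = true;
    }
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i)
    if (on_hull[i]) verts.push_back(i + 1);
  return List::create(_["volume"] = vol6 / 6.0, _["area"] = area,
                      _["faces"] = tri, _["vertices"] = wrap(verts));
}
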