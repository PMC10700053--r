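#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Piecewise-linear interpolation of scattered 2D data on a Delaunay
// triangulation (Bowyer-Watson). Sample locations are deterministically
// joggled by ~1e-9 of the coordinate range to break the collinear /
// cocircular degeneracies that exact lattice data produce (the same idea as
// qhull's joggle option); the induced interpolation error is O(1e-9 * range
// * gradient) and queries accept a matching small negative barycentric
// tolerance so hull-boundary queries are kept.

struct Tri {
  int a, b, c;
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d lies inside the circumcircle of the CCW triangle (a, b, c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

// deterministic pseudo-random in [-0.5, 0.5) from an index
static inline double jog(unsigned int i, unsigned int salt) {
  unsigned int x = i * 2654435761u + salt * 40503u + 12345u;
  x ^= x >> 13;
  x *= 1274126177u;
  x ^= x >> 16;
  return (double)(x & 0xFFFFFFu) / (double)0x1000000u - 0.5;
}

// [[Rcpp::export]]
NumericMatrix delaunay_interp_cpp(NumericVector px, NumericVector py,
                                  NumericMatrix z, NumericVector qx,
                                  NumericVector qy) {
  const int n = px.size();
  if (py.size() != n || z.nrow() != n)
    stop("point coordinates and values must have equal length");
  if (n < 3) stop("need at least 3 sample locations for triangulation");

  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double span = std::max(std::max(xmax - xmin, ymax - ymin), 1.0);
  double eps = 1e-9 * span;

  std::vector<double> X(n + 3), Y(n + 3);
  for (int i = 0; i < n; ++i) {
    X[i] = px[i] + eps * jog(i, 1u);
    Y[i] = py[i] + eps * jog(i, 2u);
  }
  // super-triangle comfortably containing every point
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax), M = 20.0 * span;
  X[n] = cx - 2.0 * M; Y[n] = cy - M;
  X[n + 1] = cx + 2.0 * M; Y[n + 1] = cy - M;
  X[n + 2] = cx; Y[n + 2] = cy + 2.0 * M;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  int nDead = 0;
  for (int i = 0; i < n; ++i) {
    // compact away dead triangles so the candidate scan stays near-linear
    if (nDead > (int)tris.size() / 2) {
      std::vector<Tri> live;
      live.reserve(tris.size() - nDead);
      for (size_t t = 0; t < tris.size(); ++t)
        if (tris[t].alive) live.push_back(tris[t]);
      tris.swap(live);
      nDead = 0;
    }
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &T = tris[t];
      if (incircle(X[T.a], Y[T.a], X[T.b], Y[T.b], X[T.c], Y[T.c],
                   X[i], Y[i]) > 0.0)
        bad.push_back(t);
    }
    // boundary of the cavity = edges used by exactly one bad triangle
    std::map<Edge, std::pair<int, Edge> > count; // sorted edge -> (count, oriented)
    for (int t : bad) {
      const Tri &T = tris[t];
      int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (int k = 0; k < 3; ++k) {
        Edge key(std::min(e[k][0], e[k][1]), std::max(e[k][0], e[k][1]));
        std::map<Edge, std::pair<int, Edge> >::iterator it = count.find(key);
        if (it == count.end())
          count[key] = std::make_pair(1, Edge(e[k][0], e[k][1]));
        else
          it->second.first += 1;
      }
      tris[t].alive = false;
      ++nDead;
    }
    for (std::map<Edge, std::pair<int, Edge> >::iterator it = count.begin();
         it != count.end(); ++it) {
      if (it->second.first != 1) continue;
      int u = it->second.second.first, v = it->second.second.second;
      Tri T = {u, v, i, true};
      if (orient2d(X[T.a], Y[T.a], X[T.b], Y[T.b], X[T.c], Y[T.c]) < 0.0)
        std::swap(T.b, T.c);
      tris.push_back(T);
    }
  }

  // keep real triangles only
  std::vector<Tri> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri &T = tris[t];
    if (T.alive && T.a < n && T.b < n && T.c < n) keep.push_back(T);
  }
  if (keep.empty())
    stop("degenerate geometry: sample locations admit no triangulation");

  // bucket grid over the bounding box for point location
  int nb = std::max(1, (int)std::sqrt((double)keep.size()));
  double bx = (xmax - xmin) / nb, by = (ymax - ymin) / nb;
  if (bx <= 0) bx = 1.0;
  if (by <= 0) by = 1.0;
  std::vector<std::vector<int> > buckets(nb * nb);
  for (int t = 0; t < (int)keep.size(); ++t) {
    const Tri &T = keep[t];
    double txmin = std::min(std::min(X[T.a], X[T.b]), X[T.c]);
    double txmax = std::max(std::max(X[T.a], X[T.b]), X[T.c]);
    double tymin = std::min(std::min(Y[T.a], Y[T.b]), Y[T.c]);
    double tymax = std::max(std::max(Y[T.a], Y[T.b]), Y[T.c]);
    int i0 = std::max(0, std::min(nb - 1, (int)((txmin - xmin) / bx)));
    int i1 = std::max(0, std::min(nb - 1, (int)((txmax - xmin) / bx)));
    int j0 = std::max(0, std::min(nb - 1, (int)((tymin - ymin) / by)));
    int j1 = std::max(0, std::min(nb - 1, (int)((tymax - ymin) / by)));
    for (int ii = i0; ii <= i1; ++ii)
      for (int jj = j0; jj <= j1; ++jj)
        buckets[ii * nb + jj].push_back(t);
  }

  const int q = qx.size(), m = z.ncol();
  NumericMatrix out(q, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double tol = -1e-5; // absorbs the joggle so hull-boundary queries are kept
  for (int iq = 0; iq < q; ++iq) {
    double x = qx[iq], y = qy[iq];
    if (x < xmin - eps * 2 || x > xmax + eps * 2 || y < ymin - eps * 2 ||
        y > ymax + eps * 2)
      continue;
    int ii = std::max(0, std::min(nb - 1, (int)((x - xmin) / bx)));
    int jj = std::max(0, std::min(nb - 1, (int)((y - ymin) / by)));
    const std::vector<int> &cand = buckets[ii * nb + jj];
    for (size_t c = 0; c < cand.size(); ++c) {
      const Tri &T = keep[cand[c]];
      double area = orient2d(X[T.a], Y[T.a], X[T.b], Y[T.b], X[T.c], Y[T.c]);
      if (area <= 0.0) continue;
      double l1 = orient2d(X[T.b], Y[T.b], X[T.c], Y[T.c], x, y) / area;
      double l2 = orient2d(X[T.c], Y[T.c], X[T.a], Y[T.a], x, y) / area;
      double l3 = 1.0 - l1 - l2;
      if (l1 >= tol && l2 >= tol && l3 >= tol) {
        double s1 = std::max(l1, 0.0), s2 = std::max(l2, 0.0),
               s3 = std::max(l3, 0.0);
        double s = s1 + s2 + s3;
        for (int k = 0; k < m; ++k)
          out(iq, k) = (s1 * z(T.a, k) + s2 * z(T.b, k) + s3 * z(T.c, k)) / s;
        break;
      }
    }
  }
  return out;
}
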