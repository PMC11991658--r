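#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// 2-d Delaunay triangulation by Bowyer-Watson incremental insertion with a
// super-triangle. O(n^2) worst case; intended for leaf-sized point sets
// (thousands of points). Coordinates are normalised internally for
// conditioning; ties on the circumcircle (cocircular quadruples) resolve to
// either diagonal, both of which are valid Delaunay triangulations.

namespace {

struct Tri {
  int a, b, c;
  double cx, cy, r2; // circumcircle
  bool alive;
};

inline void circumcircle(const std::vector<double>& px, const std::vector<double>& py,
                         Tri& t) {
  double ax = px[t.a], ay = py[t.a];
  double bx = px[t.b], by = py[t.b];
  double cx = px[t.c], cy = py[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { // collinear: infinite circumcircle
    t.cx = t.cy = 0.0;
    t.r2 = R_PosInf;
    return;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("Delaunay triangulation requires at least 3 points");

  // normalise to unit box for numerical conditioning
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y);
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (scale <= 0) stop("degenerate (zero-extent) point set");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / scale;
    py[i] = (y[i] - ymin) / scale;
  }
  // super-triangle far outside the unit box
  px[n] = -30.0;     py[n] = -30.0;
  px[n + 1] = 60.0;  py[n + 1] = -30.0;
  px[n + 2] = 0.5;   py[n + 2] = 60.0;

  std::vector<Tri> tris;
  Tri super = {n, n + 1, n + 2, 0, 0, 0, true};
  circumcircle(px, py, super);
  tris.push_back(super);

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edge_count;
  for (int i = 0; i < n; ++i) {
    double qx = px[i], qy = py[i];
    bad.clear();
    edge_count.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = qx - tris[t].cx, dy = qy - tris[t].cy;
      if (dx * dx + dy * dy < tris[t].r2) bad.push_back((int)t);
    }
    for (size_t b = 0; b < bad.size(); ++b) {
      Tri& t = tris[bad[b]];
      t.alive = false;
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int, int> key(std::min(u, v), std::max(u, v));
        edge_count[key]++;
      }
    }
    // boundary edges of the cavity appear exactly once
    for (size_t b = 0; b < bad.size(); ++b) {
      Tri t = tris[bad[b]];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int, int> key(std::min(u, v), std::max(u, v));
        if (edge_count[key] == 1) {
          Tri nt = {u, v, i, 0, 0, 0, true};
          circumcircle(px, py, nt);
          tris.push_back(nt);
        }
      }
    }
    if (bad.empty()) {
      // point outside all circumcircles (should not happen inside the super
      // triangle); duplicate points can trigger this — skip such a point
      continue;
    }
    // periodically compact the triangle list
    if (tris.size() > 16384 && i % 512 == 0) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t t = 0; t < tris.size(); ++t)
        if (tris[t].alive) keep.push_back(tris[t]);
      tris.swap(keep);
    }
  }

  std::vector<int> fa, fb, fc;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    fa.push_back(tris[t].a + 1);
    fb.push_back(tris[t].b + 1);
    fc.push_back(tris[t].c + 1);
  }
  IntegerMatrix out(fa.size(), 3);
  for (size_t i = 0; i < fa.size(); ++i) {
    out(i, 0) = fa[i];
    out(i, 1) = fb[i];
    out(i, 2) = fc[i];
  }
  return out;
}
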