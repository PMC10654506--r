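#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 2D orientation predicate: > 0 iff (a, b, c) are counter-clockwise.
static inline long double orient2d(double ax, double ay, double bx, double by,
                                   double cx, double cy) {
  return ((long double)bx - ax) * ((long double)cy - ay)
       - ((long double)by - ay) * ((long double)cx - ax);
}

// Incircle predicate for a CCW triangle (a, b, c): > 0 iff d lies strictly
// inside the circumcircle.  Exactly-cocircular quadruples evaluate to ~0 and
// are treated as "not inside", so the diagonal kept is the one created
// earlier under the fixed index-ordered insertion — a deterministic
// tie-break.
static inline long double incircle(double ax, double ay, double bx, double by,
                                   double cx, double cy, double dx, double dy) {
  const long double adx = (long double)ax - dx, ady = (long double)ay - dy;
  const long double bdx = (long double)bx - dx, bdy = (long double)by - dy;
  const long double cdx = (long double)cx - dx, cdy = (long double)cy - dy;
  const long double ad2 = adx * adx + ady * ady;
  const long double bd2 = bdx * bdx + bdy * bdy;
  const long double cd2 = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd2 - cdy * bd2)
       - ady * (bdx * cd2 - cdx * bd2)
       + ad2 * (bdx * cdy - cdx * bdy);
}

struct Tri { int a, b, c; };

// Bowyer-Watson incremental Delaunay triangulation.  Points are inserted in
// index order (deterministic).  Returns an m x 3 matrix of 1-based vertex
// indices; throws if the input is fully degenerate (all collinear).
// [[Rcpp::export]]
IntegerMatrix delaunay_triangles_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");

  // super-triangle enclosing all points by a wide margin
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0.0) span = 1.0;
  const double R = 1e3 * span;

  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  px[n]     = cx - 2.0 * R; py[n]     = cy - R;
  px[n + 1] = cx + 2.0 * R; py[n + 1] = cy - R;
  px[n + 2] = cx;           py[n + 2] = cy + 2.0 * R;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2});  // CCW

  std::vector<char> bad;
  std::vector<std::pair<int, int> > cavity;

  for (int p = 0; p < n; ++p) {
    bad.assign(tris.size(), 0);
    cavity.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      const Tri &T = tris[t];
      if (incircle(px[T.a], py[T.a], px[T.b], py[T.b],
                   px[T.c], py[T.c], px[p], py[p]) > 0.0L)
        bad[t] = 1;
    }
    // boundary of the cavity: directed edges of bad triangles whose reverse
    // is not an edge of another bad triangle
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!bad[t]) continue;
      const Tri &T = tris[t];
      const int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (int k = 0; k < 3; ++k) {
        bool shared = false;
        for (size_t s = 0; s < tris.size() && !shared; ++s) {
          if (s == t || !bad[s]) continue;
          const Tri &S = tris[s];
          const int f[3][2] = {{S.a, S.b}, {S.b, S.c}, {S.c, S.a}};
          for (int m = 0; m < 3; ++m)
            if (f[m][0] == e[k][1] && f[m][1] == e[k][0]) { shared = true; break; }
        }
        if (!shared) cavity.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    // drop bad triangles, retriangulate the cavity fan from p
    std::vector<Tri> kept;
    kept.reserve(tris.size());
    for (size_t t = 0; t < tris.size(); ++t)
      if (!bad[t]) kept.push_back(tris[t]);
    for (size_t k = 0; k < cavity.size(); ++k) {
      Tri T = {cavity[k].first, cavity[k].second, p};
      if (orient2d(px[T.a], py[T.a], px[T.b], py[T.b], px[T.c], py[T.c]) < 0.0L)
        std::swap(T.b, T.c);
      kept.push_back(T);
    }
    tris.swap(kept);
  }

  // strip triangles using super-triangle vertices
  std::vector<Tri> out;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri &T = tris[t];
    if (T.a < n && T.b < n && T.c < n) out.push_back(T);
  }
  if (out.empty()) stop("degenerate input: points are collinear");

  IntegerMatrix res(out.size(), 3);
  for (size_t t = 0; t < out.size(); ++t) {
    res(t, 0) = out[t].a + 1;
    res(t, 1) = out[t].b + 1;
    res(t, 2) = out[t].c + 1;
  }
  return res;
}
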