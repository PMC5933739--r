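// Geometric primitives used by the feature extractor and the rasterizer.
#include <RcppArmadillo.h>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Circle {
  double x, y, r2;  // centre and squared radius
};

inline bool in_circle(const Circle& c, double px, double py) {
  const double dx = px - c.x, dy = py - c.y;
  // relative slack: points on the boundary must count as inside
  return dx * dx + dy * dy <= c.r2 + 1e-10 * (1.0 + c.r2);
}

inline Circle circle_from2(double ax, double ay, double bx, double by) {
  Circle c;
  c.x = 0.5 * (ax + bx);
  c.y = 0.5 * (ay + by);
  const double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

inline Circle circle_from3(double ax, double ay, double bx, double by,
                           double cx, double cy) {
  const double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::abs(d) < 1e-14) {
    // collinear: the enclosing circle is spanned by the farthest pair
    Circle c1 = circle_from2(ax, ay, bx, by);
    Circle c2 = circle_from2(ax, ay, cx, cy);
    Circle c3 = circle_from2(bx, by, cx, cy);
    Circle best = c1;
    if (c2.r2 > best.r2) best = c2;
    if (c3.r2 > best.r2) best = c3;
    return best;
  }
  const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = cx * cx + cy * cy;
  Circle c;
  c.x = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  c.y = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  const double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

Circle trivial_circle(const std::vector<std::pair<double, double> >& r) {
  if (r.empty()) return Circle{0.0, 0.0, 0.0};
  if (r.size() == 1) return Circle{r[0].first, r[0].second, 0.0};
  if (r.size() == 2)
    return circle_from2(r[0].first, r[0].second, r[1].first, r[1].second);
  return circle_from3(r[0].first, r[0].second, r[1].first, r[1].second,
                      r[2].first, r[2].second);
}

// Welzl's move-to-front algorithm (expected linear after shuffling).
Circle welzl(std::vector<std::pair<double, double> >& pts, size_t n,
             std::vector<std::pair<double, double> > support) {
  if (n == 0 || support.size() == 3) return trivial_circle(support);
  const std::pair<double, double> p = pts[n - 1];
  Circle c = welzl(pts, n - 1, support);
  if (in_circle(c, p.first, p.second)) return c;
  support.push_back(p);
  return welzl(pts, n - 1, support);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".min_enclosing_radius")]]
double min_enclosing_radius(const arma::mat& pts) {
  const size_t n = pts.n_rows;
  if (n == 0) return 0.0;
  std::vector<std::pair<double, double> > p(n);
  for (size_t i = 0; i < n; ++i) p[i] = {pts(i, 0), pts(i, 1)};
  // deterministic shuffle so the expected-linear bound applies
  std::mt19937 rng(987654321u);
  std::shuffle(p.begin(), p.end(), rng);
  Circle c = welzl(p, p.size(), {});
  return std::sqrt(std::max(0.0, c.r2));
}

//' @noRd
// [[Rcpp::export(name = ".rasterize_cells")]]
Rcpp::IntegerMatrix rasterize_cells(const arma::mat& uv, int width, int height) {
  // uv: continuous raster coordinates, u rightward in [0,width),
  // v downward in [0,height). Marks every pixel cell the polyline passes
  // through (Amanatides-Woo grid traversal), giving a 4-connected path.
  Rcpp::IntegerMatrix img(height, width);
  const size_t n = uv.n_rows;
  if (n == 0) return img;
  auto mark = [&](long ix, long iy) {
    if (ix < 0) ix = 0;
    if (iy < 0) iy = 0;
    if (ix >= width) ix = width - 1;
    if (iy >= height) iy = height - 1;
    img(iy, ix) = 1;
  };
  mark((long)std::floor(uv(0, 0)), (long)std::floor(uv(0, 1)));
  for (size_t s = 0; s + 1 < n; ++s) {
    const double u0 = uv(s, 0), v0 = uv(s, 1);
    const double u1 = uv(s + 1, 0), v1 = uv(s + 1, 1);
    long ix = (long)std::floor(u0), iy = (long)std::floor(v0);
    const long ix1 = (long)std::floor(u1), iy1 = (long)std::floor(v1);
    const double dx = u1 - u0, dy = v1 - v0;
    const int stepx = dx > 0 ? 1 : (dx < 0 ? -1 : 0);
    const int stepy = dy > 0 ? 1 : (dy < 0 ? -1 : 0);
    const double inf = std::numeric_limits<double>::infinity();
    double tMaxX = inf, tMaxY = inf, tDeltaX = inf, tDeltaY = inf;
    if (stepx != 0) {
      const double nextX = stepx > 0 ? (double)(ix + 1) : (double)ix;
      tMaxX = (nextX - u0) / dx;
      tDeltaX = 1.0 / std::abs(dx);
    }
    if (stepy != 0) {
      const double nextY = stepy > 0 ? (double)(iy + 1) : (double)iy;
      tMaxY = (nextY - v0) / dy;
      tDeltaY = 1.0 / std::abs(dy);
    }
    mark(ix, iy);
    long guard = 4 * (std::labs(ix1 - ix) + std::labs(iy1 - iy)) + 8;
    while ((ix != ix1 || iy != iy1) && guard-- > 0) {
      if (tMaxX < tMaxY) {
        ix += stepx;
        tMaxX += tDeltaX;
      } else {
        iy += stepy;
        tMaxY += tDeltaY;
      }
      mark(ix, iy);
    }
  }
  return img;
}
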