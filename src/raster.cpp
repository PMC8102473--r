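#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Polygon rasterization under the voxel-center rule: a pixel is foreground
// iff its center (integer row/col coordinates, 0-based) lies strictly inside
// the polygon. Centers lying exactly on an edge are background. Vertices are
// continuous voxel coordinates (row, col); the polygon is closed implicitly.

static inline bool on_segment(double px, double py, double x1, double y1,
                              double x2, double y2, double eps) {
  const double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  const double len = std::hypot(x2 - x1, y2 - y1);
  if (len == 0.0) return std::hypot(px - x1, py - y1) < eps;
  if (std::fabs(cross) / len > eps) return false;
  const double dot = (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1);
  return dot >= -eps * len && dot <= len * len + eps * len;
}

// rows/cols indexed (r, c); polygon vertices (vr, vc).
// [[Rcpp::export]]
LogicalMatrix rasterize_polygon_cpp(NumericVector vr, NumericVector vc,
                                    int nrow, int ncol) {
  const int nv = vr.size();
  LogicalMatrix out(nrow, ncol);
  if (nv < 3) return out;
  const double eps = 1e-9;
  // scanline along rows: for each integer row r, x-intersections in col axis
  for (int r = 0; r < nrow; ++r) {
    std::vector<double> xs;
    for (int i = 0; i < nv; ++i) {
      const int j = (i + 1) % nv;
      double r1 = vr[i], c1 = vc[i], r2 = vr[j], c2 = vc[j];
      if (r1 == r2) continue;                 // horizontal edge: no crossing
      // half-open rule in the row coordinate
      if ((r1 <= r && r < r2) || (r2 <= r && r < r1)) {
        xs.push_back(c1 + (r - r1) / (r2 - r1) * (c2 - c1));
      }
    }
    std::sort(xs.begin(), xs.end());
    // even-odd: pixel center (r, c) inside iff odd number of crossings < c
    size_t k = 0;
    for (int c = 0; c < ncol; ++c) {
      while (k < xs.size() && xs[k] < c) ++k;
      if (k % 2 == 1) out(r, c) = true;
    }
  }
  // centers exactly on an edge are excluded ("strictly inside")
  for (int i = 0; i < nv; ++i) {
    const int j = (i + 1) % nv;
    const int rlo = std::max(0, (int)std::floor(std::min(vr[i], vr[j]) - 1));
    const int rhi = std::min(nrow - 1, (int)std::ceil(std::max(vr[i], vr[j]) + 1));
    const int clo = std::max(0, (int)std::floor(std::min(vc[i], vc[j]) - 1));
    const int chi = std::min(ncol - 1, (int)std::ceil(std::max(vc[i], vc[j]) + 1));
    for (int r = rlo; r <= rhi; ++r)
      for (int c = clo; c <= chi; ++c)
        if (out(r, c) &&
            on_segment((double)r, (double)c, vr[i], vc[i], vr[j], vc[j], 1e-9))
          out(r, c) = false;
  }
  (void)eps;
  return out;
}

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static bool seg_intersect_proper(double p1x, double p1y, double p2x, double p2y,
                                 double q1x, double q1y, double q2x, double q2y) {
  // proper crossing only: strictly opposite signs on both sides, so loops
  // that merely touch at a shared corner (pinched components) are not
  // treated as self-intersecting
  const double d1 = cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y);
  const double d2 = cross2(p2x - p1x, p2y - p1y, q2x - p1x, q2y - p1y);
  const double d3 = cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y);
  const double d4 = cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y);
  return (d1 * d2 < 0) && (d3 * d4 < 0);
}

// TRUE iff the closed polygon has a proper self-intersection between
// non-adjacent edges.
// [[Rcpp::export]]
bool polygon_self_intersects_cpp(NumericVector vr, NumericVector vc) {
  const int nv = vr.size();
  if (nv < 4) return false;
  for (int i = 0; i < nv; ++i) {
    const int i2 = (i + 1) % nv;
    for (int j = i + 1; j < nv; ++j) {
      const int j2 = (j + 1) % nv;
      if (j == i2 || j2 == i || i == j) continue;   // adjacent edges share a vertex
      if (seg_intersect_proper(vr[i], vc[i], vr[i2], vc[i2],
                               vr[j], vc[j], vr[j2], vc[j2]))
        return true;
    }
  }
  return false;
}
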