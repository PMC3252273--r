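#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fill a binary elevation x azimuth raster from triangles already projected
// onto the viewing sphere.
//
// sph: n x 6 matrix (az1, el1, az2, el2, az3, el3) in degrees. Azimuths of a
// triangle must be "unwrapped" (within 180 deg of the first vertex) so each
// triangle occupies a contiguous azimuth interval; the interval may extend
// past +-180 and is mapped back with modulo column indexing, which handles
// the wrap seam without splitting triangles.
//
// Raster layout: ncol columns span [-180, 180) deg azimuth left to right,
// nrow rows span [0, el_span] deg elevation with row 1 at the horizon.
// A pixel is set when its centre lies inside (or on the edge of) a triangle.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(NumericMatrix sph, int nrow, int ncol, double el_span) {
  IntegerMatrix img(nrow, ncol);
  const double dcol = 360.0 / ncol;
  const double drow = el_span / nrow;
  const int n = sph.nrow();

  for (int t = 0; t < n; ++t) {
    const double ax = sph(t, 0), ay = sph(t, 1);
    const double bx = sph(t, 2), by = sph(t, 3);
    const double cx = sph(t, 4), cy = sph(t, 5);

    double elmin = std::min(ay, std::min(by, cy));
    double elmax = std::max(ay, std::max(by, cy));
    if (elmax < 0.0 || elmin > el_span) continue;  // fully outside FOV

    double azmin = std::min(ax, std::min(bx, cx));
    double azmax = std::max(ax, std::max(bx, cx));

    // columns whose centres fall inside the azimuth bounding box
    int j0 = (int)std::ceil((azmin + 180.0) / dcol - 0.5);
    int j1 = (int)std::floor((azmax + 180.0) / dcol - 0.5);
    if (j1 - j0 + 1 > ncol) { j0 = 0; j1 = ncol - 1; }  // spans full circle

    const double ex_[3] = {ax, bx, cx};
    const double ey_[3] = {ay, by, cy};

    // per-column scanline: a pixel centre (px, py) lies in the (convex)
    // triangle iff py is between the triangle's edge crossings at az = px
    for (int jj = j0; jj <= j1; ++jj) {
      const double px = -180.0 + (jj + 0.5) * dcol;
      double lo = 0, hi = 0;
      bool any = false;
      for (int e = 0; e < 3; ++e) {
        const double x1 = ex_[e], y1 = ey_[e];
        const double x2 = ex_[(e + 1) % 3], y2 = ey_[(e + 1) % 3];
        if ((x1 - px) * (x2 - px) > 0) continue;   // edge misses the column
        double ylo, yhi;
        if (x1 == x2) {                            // edge lies on the column
          ylo = std::min(y1, y2); yhi = std::max(y1, y2);
        } else {
          const double t = (px - x1) / (x2 - x1);
          ylo = yhi = y1 + t * (y2 - y1);
        }
        if (!any) { lo = ylo; hi = yhi; any = true; }
        else {
          if (ylo < lo) lo = ylo;
          if (yhi > hi) hi = yhi;
        }
      }
      if (!any) continue;
      int i0 = (int)std::ceil(lo / drow - 0.5);
      int i1 = (int)std::floor(hi / drow - 0.5);
      if (i0 < 0) i0 = 0;
      if (i1 > nrow - 1) i1 = nrow - 1;
      if (i0 > i1) continue;
      int col = jj % ncol;
      if (col < 0) col += ncol;
      for (int ii = i0; ii <= i1; ++ii) img(ii, col) = 1;
    }
  }
  return img;
}

// Project patch vertices into the eye-centred spherical frame.
//
// patches: n x 9 (x1,y1,z1,...,z3) world coordinates. Returns an n' x 6
// matrix (az1, el1, ..., el3) in degrees with azimuth relative to
// `heading` (clockwise from north) and triangle azimuths unwrapped to be
// mutually continuous; rows whose vertex coincides with the eye point are
// dropped and counted in the "skipped" attribute.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericMatrix patches, double ex, double ey,
                          double ez, double heading) {
  const int n = patches.nrow();
  const double rad2deg = 180.0 / M_PI;
  NumericMatrix out(n, 6);
  int kept = 0, skipped = 0;
  for (int i = 0; i < n; ++i) {
    double az[3], el[3];
    bool degen = false;
    for (int v = 0; v < 3; ++v) {
      const double dx = patches(i, 3 * v) - ex;
      const double dy = patches(i, 3 * v + 1) - ey;
      const double dz = patches(i, 3 * v + 2) - ez;
      const double hor = std::sqrt(dx * dx + dy * dy);
      const double r = std::sqrt(hor * hor + dz * dz);
      if (r < 1e-9) { degen = true; break; }
      // pole convention: azimuth 0 for points directly over/under the eye
      double a = (hor < 1e-12) ? 0.0 : std::atan2(dx, dy) * rad2deg;
      a -= heading;
      az[v] = a - 360.0 * std::floor((a + 180.0) / 360.0);  // [-180, 180)
      el[v] = std::atan2(dz, hor) * rad2deg;
    }
    if (degen) { ++skipped; continue; }
    for (int v = 1; v < 3; ++v) {   // unwrap towards vertex 1
      const double d = az[v] - az[0];
      az[v] = az[0] + d - 360.0 * std::floor((d + 180.0) / 360.0);
    }
    out(kept, 0) = az[0]; out(kept, 1) = el[0];
    out(kept, 2) = az[1]; out(kept, 3) = el[1];
    out(kept, 4) = az[2]; out(kept, 5) = el[2];
    ++kept;
  }
  NumericMatrix res = (kept == n) ? out :
    NumericMatrix(Dimension(kept, 6));
  if (kept != n) {
    for (int j = 0; j < 6; ++j)
      for (int i = 0; i < kept; ++i)
        res(i, j) = out(i, j);
  }
  res.attr("skipped") = skipped;
  return res;
}

// One natural-gradient Infomax learning step:
//   h = W x, y = tanh(h), W_out = W + scale * (W - (y + h) h^T W).
// Kept in C++ because the R expression makes ~6 full passes over the
// M x N weight matrix in temporaries; this makes 2.
// [[Rcpp::export]]
NumericMatrix cpp_infomax_step(NumericMatrix W, NumericVector x, double scale) {
  const int M = W.nrow(), N = W.ncol();
  std::vector<double> h(M), g(M), hW(N, 0.0);
  for (int j = 0; j < N; ++j) {
    const double xj = x[j];
    const double* wj = &W(0, j);
    for (int i = 0; i < M; ++i) {
      h[i] += wj[i] * xj;   // accumulate W x column-wise
    }
  }
  for (int i = 0; i < M; ++i) g[i] = std::tanh(h[i]) + h[i];
  for (int j = 0; j < N; ++j) {
    const double* wj = &W(0, j);
    double s = 0.0;
    for (int i = 0; i < M; ++i) s += h[i] * wj[i];
    hW[j] = s;
  }
  NumericMatrix out(M, N);
  for (int j = 0; j < N; ++j) {
    const double* wj = &W(0, j);
    double* oj = &out(0, j);
    const double hWj = hW[j];
    for (int i = 0; i < M; ++i) {
      oj[i] = wj[i] + scale * (wj[i] - g[i] * hWj);
    }
  }
  return out;
}

// Block-average a binary raster down to a nrow_out x ncol_out grey image.
// Kept in C++ because it sits inside the per-step rendering loop.
// [[Rcpp::export]]
NumericMatrix cpp_block_average(IntegerMatrix h, int nrow_out, int ncol_out) {
  const int nr = h.nrow(), nc = h.ncol();
  const int kr = nr / nrow_out, kc = nc / ncol_out;
  NumericMatrix out(nrow_out, ncol_out);
  for (int j = 0; j < nc; ++j) {
    const int oj = j / kc;
    for (int i = 0; i < nr; ++i) {
      out(i / kr, oj) += h(i, j);
    }
  }
  const double denom = (double)kr * kc;
  for (int j = 0; j < ncol_out; ++j)
    for (int i = 0; i < nrow_out; ++i)
      out(i, j) /= denom;
  return out;
}
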