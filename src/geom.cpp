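// Low-level raster/distance primitives for 2D contour geometry.
// Polygons are open rings: n x 2 matrices in mm, implicitly closed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline bool point_in_poly(double px, double py, const NumericMatrix &P) {
  // even-odd crossing rule; boundary points count as inside
  int n = P.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = P(i, 0), yi = P(i, 1), xj = P(j, 0), yj = P(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

static inline double seg_dist(double px, double py, double ax, double ay,
                              double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double ex = ax + t * dx - px, ey = ay + t * dy - py;
  return std::sqrt(ex * ex + ey * ey);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericMatrix pts, NumericMatrix poly) {
  int m = pts.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = point_in_poly(pts(i, 0), pts(i, 1), poly);
  return out;
}

// Binary mask over grid centers xs x ys: 1 iff center inside polygon.
// [[Rcpp::export]]
IntegerMatrix cpp_pip_mask(NumericMatrix poly, NumericVector xs,
                           NumericVector ys) {
  int nx = xs.size(), ny = ys.size(), n = poly.nrow();
  IntegerMatrix out(nx, ny);
  // scanline over y: find x-crossings of each horizontal line, then mark runs
  std::vector<double> cross;
  for (int j = 0; j < ny; ++j) {
    double py = ys[j];
    cross.clear();
    for (int i = 0, k = n - 1; i < n; k = i++) {
      double yi = poly(i, 1), yk = poly(k, 1);
      if ((yi > py) != (yk > py)) {
        double xi = poly(i, 0), xk = poly(k, 0);
        cross.push_back(xk + (py - yk) * (xi - xk) / (yi - yk));
      }
    }
    std::sort(cross.begin(), cross.end());
    // inside between crossing pairs
    for (size_t c = 0; c + 1 < cross.size(); c += 2) {
      double x0 = cross[c], x1 = cross[c + 1];
      int i0 = int(std::lower_bound(xs.begin(), xs.end(), x0) - xs.begin());
      for (int i = i0; i < nx && xs[i] < x1; ++i) out(i, j) = 1;
    }
  }
  return out;
}

// Min Euclidean distance from each point to the polygon boundary.
// [[Rcpp::export]]
NumericVector cpp_dist_to_poly(NumericMatrix pts, NumericMatrix poly) {
  int m = pts.nrow(), n = poly.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf;
    for (int a = 0, b = n - 1; a < n; b = a++) {
      double d = seg_dist(px, py, poly(b, 0), poly(b, 1), poly(a, 0), poly(a, 1));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// 1D lower-envelope distance transform (Felzenszwalb & Huttenlocher) over
// arbitrary sample positions x[]; f holds squared distances.
static void dt1d(std::vector<double> &f, const std::vector<double> &x) {
  int n = f.size();
  std::vector<int> v(n);
  std::vector<double> zz(n + 1), out(n);
  int k = 0;
  v[0] = 0;
  zz[0] = -1e300; zz[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
          (2 * x[q] - 2 * x[p]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < x[q]) ++k;
    double d = x[q] - x[v[k]];
    out[q] = d * d + f[v[k]];
  }
  f = out;
}

// Signed distance over grid centers: negative inside, positive outside.
// Exact distance to a dense boundary sampling (step = half a grid cell),
// propagated by an exact Euclidean distance transform; the approximation
// error is below one grid step.
// [[Rcpp::export]]
NumericMatrix cpp_sdf_grid(NumericMatrix poly, NumericVector xs,
                           NumericVector ys) {
  int nx = xs.size(), ny = ys.size(), n = poly.nrow();
  double dx = nx > 1 ? xs[1] - xs[0] : 1.0;
  double dy = ny > 1 ? ys[1] - ys[0] : 1.0;
  double h = 0.5 * std::min(dx, dy);
  std::vector<double> F((size_t)nx * ny, 1e30);
  // seed cells with squared distance to boundary samples
  for (int a = 0, b = n - 1; a < n; b = a++) {
    double ax = poly(b, 0), ay = poly(b, 1);
    double ex = poly(a, 0) - ax, ey = poly(a, 1) - ay;
    double len = std::sqrt(ex * ex + ey * ey);
    int ns = std::max(1, (int)std::ceil(len / h));
    for (int s = 0; s <= ns; ++s) {
      double t = (double)s / ns;
      double px = ax + t * ex, py = ay + t * ey;
      int i = (int)std::lround((px - xs[0]) / dx);
      int j = (int)std::lround((py - ys[0]) / dy);
      if (i < 0) i = 0; if (i >= nx) i = nx - 1;
      if (j < 0) j = 0; if (j >= ny) j = ny - 1;
      double ddx = px - xs[i], ddy = py - ys[j];
      double d2 = ddx * ddx + ddy * ddy;
      double &cell = F[i + (size_t)j * nx];
      if (d2 < cell) cell = d2;
    }
  }
  // EDT: columns (x direction), then rows (y direction)
  std::vector<double> colx(nx), coly(ny), buf;
  for (int i = 0; i < nx; ++i) colx[i] = xs[i];
  for (int j = 0; j < ny; ++j) coly[j] = ys[j];
  buf.resize(nx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) buf[i] = F[i + (size_t)j * nx];
    dt1d(buf, colx);
    for (int i = 0; i < nx; ++i) F[i + (size_t)j * nx] = buf[i];
  }
  buf.resize(ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) buf[j] = F[i + (size_t)j * nx];
    dt1d(buf, coly);
    for (int j = 0; j < ny; ++j) F[i + (size_t)j * nx] = buf[j];
  }
  // sign by scanline parity (matches cpp_pip_mask)
  NumericMatrix out(nx, ny);
  std::vector<double> cross;
  for (int j = 0; j < ny; ++j) {
    double py = ys[j];
    cross.clear();
    for (int i2 = 0, k2 = n - 1; i2 < n; k2 = i2++) {
      double yi = poly(i2, 1), yk = poly(k2, 1);
      if ((yi > py) != (yk > py)) {
        double xi = poly(i2, 0), xk = poly(k2, 0);
        cross.push_back(xk + (py - yk) * (xi - xk) / (yi - yk));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (int i = 0; i < nx; ++i) {
      bool inside = false;
      for (size_t c = 0; c + 1 < cross.size(); c += 2)
        if (xs[i] >= cross[c] && xs[i] < cross[c + 1]) { inside = true; break; }
      double d = std::sqrt(F[i + (size_t)j * nx]);
      out(i, j) = inside ? -d : d;
    }
  }
  return out;
}

// Largest 4-connected component of a binary matrix; returns binary matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_largest_component(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0, best_lab = 0, best_n = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (mask(i, j) && !lab(i, j)) {
      ++next; int cnt = 0;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        ++cnt;
        const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          int qi = pi + di[d], qj = pj + dj[d];
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
              mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
      if (cnt > best_n) { best_n = cnt; best_lab = next; }
    }
  }
  IntegerMatrix out(nr, nc);
  if (best_lab > 0)
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i)
      out(i, j) = lab(i, j) == best_lab ? 1 : 0;
  return out;
}

// Separable Gaussian blur, reflective borders, sigma in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) a += k[d + r] * img(refl(i + d, nr), j);
      tmp(i, j) = a;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) a += k[d + r] * tmp(i, refl(j + d, nc));
      out(i, j) = a;
    }
  return out;
}

// Bilinear sampling of img at fractional (1-based) row/col positions.
// Out-of-range positions get `fill`. Used for resizing and affine warps.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector ri,
                                  NumericVector ci, double fill) {
  int nr = img.nrow(), nc = img.ncol(), m = ri.size();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double r = ri[p] - 1.0, c = ci[p] - 1.0;
    if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) { out[p] = fill; continue; }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
    double fr = r - r0, fc = c - c0;
    out[p] = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
             fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
  }
  return out;
}

// Nearest-neighbour sampling (for label images).
// [[Rcpp::export]]
NumericVector cpp_nearest_sample(NumericMatrix img, NumericVector ri,
                                 NumericVector ci, double fill) {
  int nr = img.nrow(), nc = img.ncol(), m = ri.size();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    int r = (int)std::lround(ri[p]) - 1, c = (int)std::lround(ci[p]) - 1;
    out[p] = (r < 0 || c < 0 || r >= nr || c >= nc) ? fill : img(r, c);
  }
  return out;
}
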