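#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact line integral of a piecewise-constant 2-D image along the ray
// p + t*u (u unit vector), via Amanatides-Woo voxel traversal.
// Image is nx x ny, column-major (x fastest), voxel size d (mm), voxel
// (i,j) centered at ((i-(nx-1)/2)*d, (j-(ny-1)/2)*d). Returns integral in
// value * mm.
static double ray_integral(const double *img, int nx, int ny, double d,
                           double px, double py, double ux, double uy) {
  const double xmin = -0.5 * nx * d, xmax = 0.5 * nx * d;
  const double ymin = -0.5 * ny * d, ymax = 0.5 * ny * d;
  const double inf = std::numeric_limits<double>::infinity();

  double t0 = -inf, t1 = inf;
  if (std::fabs(ux) < 1e-12) {
    if (px <= xmin || px >= xmax) return 0.0;
  } else {
    double ta = (xmin - px) / ux, tb = (xmax - px) / ux;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(uy) < 1e-12) {
    if (py <= ymin || py >= ymax) return 0.0;
  } else {
    double ta = (ymin - py) / uy, tb = (ymax - py) / uy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (t1 <= t0) return 0.0;

  // entry voxel (nudge inside to avoid landing exactly on the boundary)
  double tcur = t0;
  double xs = px + (t0 + 1e-9) * ux, ys = py + (t0 + 1e-9) * uy;
  int i = (int)std::floor((xs - xmin) / d);
  int j = (int)std::floor((ys - ymin) / d);
  if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
  if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;

  int stepx = (ux > 0) ? 1 : -1, stepy = (uy > 0) ? 1 : -1;
  double tdx = (std::fabs(ux) < 1e-12) ? inf : d / std::fabs(ux);
  double tdy = (std::fabs(uy) < 1e-12) ? inf : d / std::fabs(uy);
  double tmx, tmy;
  if (std::fabs(ux) < 1e-12) tmx = inf;
  else {
    double bx = xmin + (i + (stepx > 0 ? 1 : 0)) * d;
    tmx = (bx - px) / ux;
  }
  if (std::fabs(uy) < 1e-12) tmy = inf;
  else {
    double by = ymin + (j + (stepy > 0 ? 1 : 0)) * d;
    tmy = (by - py) / uy;
  }

  double acc = 0.0;
  while (tcur < t1 - 1e-12) {
    double tnext = std::min(std::min(tmx, tmy), t1);
    if (tnext > tcur && i >= 0 && i < nx && j >= 0 && j < ny)
      acc += (tnext - tcur) * img[i + (size_t)j * nx];
    tcur = tnext;
    if (tmx <= tmy) { i += stepx; tmx += tdx; }
    else            { j += stepy; tmy += tdy; }
    if (i < 0 || i >= nx || j < 0 || j >= ny) break;
  }
  return acc;
}

// Adjoint: spread sino value along the same ray with identical weights.
static void ray_backproject(double *img, int nx, int ny, double d,
                            double px, double py, double ux, double uy,
                            double val) {
  const double xmin = -0.5 * nx * d, xmax = 0.5 * nx * d;
  const double ymin = -0.5 * ny * d, ymax = 0.5 * ny * d;
  const double inf = std::numeric_limits<double>::infinity();

  double t0 = -inf, t1 = inf;
  if (std::fabs(ux) < 1e-12) {
    if (px <= xmin || px >= xmax) return;
  } else {
    double ta = (xmin - px) / ux, tb = (xmax - px) / ux;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(uy) < 1e-12) {
    if (py <= ymin || py >= ymax) return;
  } else {
    double ta = (ymin - py) / uy, tb = (ymax - py) / uy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (t1 <= t0) return;

  double tcur = t0;
  double xs = px + (t0 + 1e-9) * ux, ys = py + (t0 + 1e-9) * uy;
  int i = (int)std::floor((xs - xmin) / d);
  int j = (int)std::floor((ys - ymin) / d);
  if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
  if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;

  int stepx = (ux > 0) ? 1 : -1, stepy = (uy > 0) ? 1 : -1;
  double tdx = (std::fabs(ux) < 1e-12) ? inf : d / std::fabs(ux);
  double tdy = (std::fabs(uy) < 1e-12) ? inf : d / std::fabs(uy);
  double tmx, tmy;
  if (std::fabs(ux) < 1e-12) tmx = inf;
  else tmx = (xmin + (i + (stepx > 0 ? 1 : 0)) * d - px) / ux;
  if (std::fabs(uy) < 1e-12) tmy = inf;
  else tmy = (ymin + (j + (stepy > 0 ? 1 : 0)) * d - py) / uy;

  while (tcur < t1 - 1e-12) {
    double tnext = std::min(std::min(tmx, tmy), t1);
    if (tnext > tcur && i >= 0 && i < nx && j >= 0 && j < ny)
      img[i + (size_t)j * nx] += (tnext - tcur) * val;
    tcur = tnext;
    if (tmx <= tmy) { i += stepx; tmx += tdx; }
    else            { j += stepy; tmy += tdy; }
    if (i < 0 || i >= nx || j < 0 || j >= ny) break;
  }
}

// [[Rcpp::export]]
double cpp_ray_integral(NumericMatrix img, double d, double px, double py,
                        double ux, double uy) {
  double n = std::sqrt(ux * ux + uy * uy);
  return ray_integral(REAL(img), img.nrow(), img.ncol(), d, px, py,
                      ux / n, uy / n);
}

// Parallel-beam sinogram of one slice: rows = angles, cols = radial bins.
// Radial bin k (0-based) sits at s = (k - (nrad-1)/2) * d.
// [[Rcpp::export]]
NumericMatrix cpp_project_slice(NumericMatrix img, NumericVector angles,
                                int nrad, double d) {
  int nx = img.nrow(), ny = img.ncol(), na = angles.size();
  NumericMatrix out(na, nrad);
  const double *p = REAL(img);
  for (int a = 0; a < na; ++a) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int k = 0; k < nrad; ++k) {
      double r = (k - 0.5 * (nrad - 1)) * d;
      out(a, k) = ray_integral(p, nx, ny, d, -r * s, r * c, c, s);
    }
  }
  return out;
}

// Exact adjoint of cpp_project_slice.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_slice(NumericMatrix sino, NumericVector angles,
                                    int nx, int ny, double d) {
  int na = angles.size(), nrad = sino.ncol();
  NumericMatrix out(nx, ny);
  double *p = REAL(out);
  for (int a = 0; a < na; ++a) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int k = 0; k < nrad; ++k) {
      double v = sino(a, k);
      if (v == 0.0) continue;
      double r = (k - 0.5 * (nrad - 1)) * d;
      ray_backproject(p, nx, ny, d, -r * s, r * c, c, s, v);
    }
  }
  return out;
}

// Slice-by-slice volume projection: vol is nx*ny*nz (column-major),
// output is na*nrad*nz.
// [[Rcpp::export]]
NumericVector cpp_project_vol(NumericVector vol, IntegerVector dims,
                              NumericVector angles, int nrad, double d) {
  int nx = dims[0], ny = dims[1], nz = dims[2], na = angles.size();
  NumericVector out((size_t)na * nrad * nz);
  std::vector<double> ca(na), sa(na);
  for (int a = 0; a < na; ++a) { ca[a] = std::cos(angles[a]); sa[a] = std::sin(angles[a]); }
  const double *v = REAL(vol);
  double *o = REAL(out);
  size_t pslice = (size_t)nx * ny, sslice = (size_t)na * nrad;
  for (int z = 0; z < nz; ++z) {
    const double *img = v + z * pslice;
    double *sl = o + z * sslice;
    for (int a = 0; a < na; ++a)
      for (int k = 0; k < nrad; ++k) {
        double r = (k - 0.5 * (nrad - 1)) * d;
        sl[a + (size_t)k * na] =
          ray_integral(img, nx, ny, d, -r * sa[a], r * ca[a], ca[a], sa[a]);
      }
  }
  out.attr("dim") = IntegerVector::create(na, nrad, nz);
  return out;
}

// Slice-by-slice volume backprojection over a subset of angles.
// sino is na*nrad*nz; angle_idx selects rows (0-based).
// [[Rcpp::export]]
NumericVector cpp_backproject_vol(NumericVector sino, IntegerVector sdims,
                                  IntegerVector angle_idx,
                                  NumericVector angles, IntegerVector dims,
                                  double d) {
  int na = sdims[0], nrad = sdims[1], nz = sdims[2];
  int nx = dims[0], ny = dims[1];
  NumericVector out((size_t)nx * ny * nz);
  const double *s = REAL(sino);
  double *o = REAL(out);
  size_t pslice = (size_t)nx * ny, sslice = (size_t)na * nrad;
  for (int z = 0; z < nz; ++z) {
    double *img = o + z * pslice;
    const double *sl = s + z * sslice;
    for (int ai = 0; ai < angle_idx.size(); ++ai) {
      int a = angle_idx[ai];
      double c = std::cos(angles[a]), sn = std::sin(angles[a]);
      for (int k = 0; k < nrad; ++k) {
        double val = sl[a + (size_t)k * na];
        if (val == 0.0) continue;
        double r = (k - 0.5 * (nrad - 1)) * d;
        ray_backproject(img, nx, ny, d, -r * sn, r * c, c, sn, val);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Subset projection: project one slice stack over selected angles only.
// [[Rcpp::export]]
NumericVector cpp_project_vol_subset(NumericVector vol, IntegerVector dims,
                                     IntegerVector angle_idx,
                                     NumericVector angles, int na_total,
                                     int nrad, double d) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)na_total * nrad * nz); // zeros outside subset
  const double *v = REAL(vol);
  double *o = REAL(out);
  size_t pslice = (size_t)nx * ny, sslice = (size_t)na_total * nrad;
  for (int z = 0; z < nz; ++z) {
    const double *img = v + z * pslice;
    double *sl = o + z * sslice;
    for (int ai = 0; ai < angle_idx.size(); ++ai) {
      int a = angle_idx[ai];
      double c = std::cos(angles[a]), sn = std::sin(angles[a]);
      for (int k = 0; k < nrad; ++k) {
        double r = (k - 0.5 * (nrad - 1)) * d;
        sl[a + (size_t)k * na_total] =
          ray_integral(img, nx, ny, d, -r * sn, r * c, c, sn);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(na_total, nrad, nz);
  return out;
}

// Dice overlap between binary mask A (fixed) and integer-shifted mask B,
// for each candidate shift (rows of `shifts`, voxel units, applied to B).
// |B| is counted over the part of shifted B that lands inside the grid.
// [[Rcpp::export]]
NumericVector cpp_shift_dice(IntegerVector A, IntegerVector B,
                             IntegerVector dims, IntegerMatrix shifts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *a = INTEGER(A), *b = INTEGER(B);
  int ns = shifts.nrow();
  NumericVector dice(ns);
  long nA = 0;
  size_t n = (size_t)nx * ny * nz;
  for (size_t i = 0; i < n; ++i) nA += a[i];
  for (int si = 0; si < ns; ++si) {
    int dx = shifts(si, 0), dy = shifts(si, 1), dz = shifts(si, 2);
    long ov = 0, nB = 0;
    int x0 = std::max(0, dx), x1 = std::min(nx, nx + dx);
    int y0 = std::max(0, dy), y1 = std::min(ny, ny + dy);
    int z0 = std::max(0, dz), z1 = std::min(nz, nz + dz);
    for (int z = z0; z < z1; ++z)
      for (int y = y0; y < y1; ++y) {
        size_t rowA = (size_t)y * nx + (size_t)z * nx * ny;
        size_t rowB = (size_t)(y - dy) * nx + (size_t)(z - dz) * nx * ny;
        for (int x = x0; x < x1; ++x) {
          int bv = b[(size_t)(x - dx) + rowB];
          nB += bv;
          ov += bv & a[(size_t)x + rowA];
        }
      }
    dice[si] = (nA + nB > 0) ? 2.0 * ov / (double)(nA + nB) : 0.0;
  }
  return dice;
}

// 6-connected component labelling of a binary 3-D mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const int *m = INTEGER(mask);
  IntegerVector lab(n);
  int *l = INTEGER(lab);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || l[s]) continue;
    ++next;
    stack.push_back(s);
    l[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t idx = (size_t)xx + (size_t)yy * nx + (size_t)zz * nx * ny;
        if (m[idx] && !l[idx]) { l[idx] = next; stack.push_back(idx); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
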