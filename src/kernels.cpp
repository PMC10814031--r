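#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Voxel (i,j,k) 0-based, column-major: idx = i + j*n1 + k*n1*n2.
// World coordinate of voxel center: origin + index*spacing.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3D,
// anisotropic spacing, distances in mm between voxel centers.
// ---------------------------------------------------------------------------

// 1D squared-distance transform along a line with sample spacing w.
// f: input squared distances at positions 0, w, 2w, ...; d: output.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      // intersection of parabolas from v[k] and q
      double num = (f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k]);
      s = num / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector obstacle, IntegerVector dim,
                        NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  // background starts at a huge finite squared distance (not infinity, so
  // parabola intersections on obstacle-free scan lines stay defined)
  const double BIG = 1e15;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obstacle[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* col = &out[(R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2];
      for (int i = 0; i < n1; ++i) f[i] = col[i];
      dt1d(f.data(), d.data(), n1, spacing[0], v, z);
      for (int i = 0; i < n1; ++i) col[i] = d[i];
    }
  // pass along y (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)k * n1 * n2;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f.data(), d.data(), n2, spacing[1], v, z);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }
  // pass along z (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)j * n1;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * s3];
      dt1d(f.data(), d.data(), n3, spacing[2], v, z);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * s3] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (sigma in voxels, reflected boundaries).
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double>& a, int n1, int n2, int n3,
                        int axis, const std::vector<double>& kern) {
  const int r = ((int)kern.size() - 1) / 2;
  const R_xlen_t s[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
  const int len[3] = {n1, n2, n3};
  const int nl = len[axis];
  std::vector<double> line(nl);
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < len[ob]; ++b)
    for (int aI = 0; aI < len[oa]; ++aI) {
      R_xlen_t base = (R_xlen_t)aI * s[oa] + (R_xlen_t)b * s[ob];
      for (int q = 0; q < nl; ++q) line[q] = a[base + (R_xlen_t)q * s[axis]];
      for (int q = 0; q < nl; ++q) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = q + t;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= nl) p = 2 * nl - p - 1;
          acc += kern[t + r] * line[p];
        }
        a[base + (R_xlen_t)q * s[axis]] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector x, IntegerVector dim, double sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (auto& k : kern) k /= s;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = x[i];
  for (int axis = 0; axis < 3; ++axis) smooth_axis(a, n1, n2, n3, axis, kern);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i];
  return out;
}

// ---------------------------------------------------------------------------
// Ray sampling over a labeled volume.
// ---------------------------------------------------------------------------

static inline int label_at(const int* lab, int n1, int n2, int n3,
                           const double* sp, const double* org,
                           double x, double y, double z) {
  int i = clampi((int)std::lround((x - org[0]) / sp[0]), 0, n1 - 1);
  int j = clampi((int)std::lround((y - org[1]) / sp[1]), 0, n2 - 1);
  int k = clampi((int)std::lround((z - org[2]) / sp[2]), 0, n3 - 1);
  return lab[i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2];
}

static inline bool in_set(int lab, const LogicalVector& set) {
  return lab >= 0 && lab < set.size() && set[lab];
}

// First crossing into label set along each segment start->end, sampled at
// step_mm and refined by bisection to within tol_mm of the boundary.
// Returns N x 5 matrix: hit(0/1), t_mm from start, point x, y, z.
// [[Rcpp::export]]
NumericMatrix cpp_first_hit(IntegerVector labels, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix starts, NumericMatrix ends,
                            LogicalVector set, double step_mm, double tol_mm) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int N = starts.nrow();
  const int* lab = INTEGER(labels);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  NumericMatrix out(N, 5);
  for (int r = 0; r < N; ++r) {
    double ox = starts(r, 0), oy = starts(r, 1), oz = starts(r, 2);
    double dx = ends(r, 0) - ox, dy = ends(r, 1) - oy, dz = ends(r, 2) - oz;
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    out(r, 0) = 0.0;
    if (len <= 0) continue;
    dx /= len; dy /= len; dz /= len;
    int ns = (int)std::ceil(len / step_mm);
    double tprev = 0.0;
    bool prev_in = in_set(label_at(lab, n1, n2, n3, sp, org, ox, oy, oz), set);
    if (prev_in) {
      out(r, 0) = 1.0; out(r, 1) = 0.0;
      out(r, 2) = ox; out(r, 3) = oy; out(r, 4) = oz;
      continue;
    }
    double thit = -1.0;
    for (int s = 1; s <= ns; ++s) {
      double t = std::min(len, s * step_mm);
      bool cur = in_set(label_at(lab, n1, n2, n3, sp, org,
                                 ox + t * dx, oy + t * dy, oz + t * dz), set);
      if (cur) {
        // bisect (tprev, t]: tprev outside set, t inside
        double lo = tprev, hi = t;
        while (hi - lo > tol_mm) {
          double mid = 0.5 * (lo + hi);
          if (in_set(label_at(lab, n1, n2, n3, sp, org,
                              ox + mid * dx, oy + mid * dy, oz + mid * dz),
                     set))
            hi = mid;
          else
            lo = mid;
        }
        thit = hi;
        break;
      }
      tprev = t;
    }
    if (thit >= 0) {
      out(r, 0) = 1.0; out(r, 1) = thit;
      out(r, 2) = ox + thit * dx; out(r, 3) = oy + thit * dy;
      out(r, 4) = oz + thit * dz;
    }
  }
  return out;
}

// Trilinear interpolation of a scalar field at one point (clamped).
static inline double trilin(const double* f, int n1, int n2, int n3,
                            const double* sp, const double* org,
                            double x, double y, double z) {
  double u = (x - org[0]) / sp[0], v = (y - org[1]) / sp[1],
         w = (z - org[2]) / sp[2];
  u = std::min(std::max(u, 0.0), (double)(n1 - 1));
  v = std::min(std::max(v, 0.0), (double)(n2 - 1));
  w = std::min(std::max(w, 0.0), (double)(n3 - 1));
  int i0 = std::min((int)u, n1 - 2 < 0 ? 0 : n1 - 2);
  int j0 = std::min((int)v, n2 - 2 < 0 ? 0 : n2 - 2);
  int k0 = std::min((int)w, n3 - 2 < 0 ? 0 : n3 - 2);
  double fu = u - i0, fv = v - j0, fw = w - k0;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const double* p = f + i0 + (R_xlen_t)j0 * s2 + (R_xlen_t)k0 * s3;
  int i1 = (n1 > 1) ? 1 : 0, j1 = (n2 > 1) ? (int)s2 : 0,
      k1 = (n3 > 1) ? (int)s3 : 0;
  double c00 = p[0] * (1 - fu) + p[i1] * fu;
  double c10 = p[j1] * (1 - fu) + p[j1 + i1] * fu;
  double c01 = p[k1] * (1 - fu) + p[k1 + i1] * fu;
  double c11 = p[j1 + k1] * (1 - fu) + p[j1 + k1 + i1] * fu;
  double c0 = c00 * (1 - fv) + c10 * fv;
  double c1 = c01 * (1 - fv) + c11 * fv;
  return c0 * (1 - fw) + c1 * fw;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  const int N = pts.nrow();
  NumericVector out(N);
  const double* f = REAL(field);
  for (int r = 0; r < N; ++r)
    out[r] = trilin(f, dim[0], dim[1], dim[2], REAL(spacing), REAL(origin),
                    pts(r, 0), pts(r, 1), pts(r, 2));
  return out;
}

// Minimum (want_min) or maximum of interpolated field values over uniform
// samples (both endpoints included) along each segment. Interpolation is
// trilinear by default; `nearest = true` reads the nearest voxel instead
// (voxel-level projection semantics).
// [[Rcpp::export]]
NumericVector cpp_seg_extreme(NumericVector field, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix starts, NumericMatrix ends,
                              double step_mm, bool want_min,
                              bool nearest = false) {
  const int N = starts.nrow();
  NumericVector out(N);
  const double* f = REAL(field);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  auto value_at = [&](double x, double y, double z) {
    if (nearest) {
      int i = clampi((int)std::lround((x - org[0]) / sp[0]), 0, n1 - 1);
      int j = clampi((int)std::lround((y - org[1]) / sp[1]), 0, n2 - 1);
      int k = clampi((int)std::lround((z - org[2]) / sp[2]), 0, n3 - 1);
      return f[i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2];
    }
    return trilin(f, n1, n2, n3, sp, org, x, y, z);
  };
  for (int r = 0; r < N; ++r) {
    double ox = starts(r, 0), oy = starts(r, 1), oz = starts(r, 2);
    double dx = ends(r, 0) - ox, dy = ends(r, 1) - oy, dz = ends(r, 2) - oz;
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    int ns = (len > 0) ? (int)std::ceil(len / step_mm) : 0;
    double best = value_at(ox, oy, oz);
    for (int s = 1; s <= ns; ++s) {
      double t = std::min(len, s * step_mm);
      double v = value_at(ox + t * dx / len, oy + t * dy / len,
                          oz + t * dz / len);
      if (want_min ? (v < best) : (v > best)) best = v;
    }
    out[r] = best;
  }
  return out;
}

// First crossing of the trilinearly interpolated field above `thresh` along
// each segment, sampled at step_mm and refined by bisection to tol_mm.
// Returns N x 5: hit(0/1), t_mm, point x, y, z.
// [[Rcpp::export]]
NumericMatrix cpp_first_iso(NumericVector field, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix starts, NumericMatrix ends,
                            double step_mm, double thresh, double tol_mm) {
  const int N = starts.nrow();
  const double* f = REAL(field);
  const double* sp = REAL(spacing);
  const double* org = REAL(origin);
  NumericMatrix out(N, 5);
  for (int r = 0; r < N; ++r) {
    double ox = starts(r, 0), oy = starts(r, 1), oz = starts(r, 2);
    double dx = ends(r, 0) - ox, dy = ends(r, 1) - oy, dz = ends(r, 2) - oz;
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    out(r, 0) = 0.0;
    if (len <= 0) continue;
    dx /= len; dy /= len; dz /= len;
    if (trilin(f, dim[0], dim[1], dim[2], sp, org, ox, oy, oz) >= thresh) {
      out(r, 0) = 1.0; out(r, 1) = 0.0;
      out(r, 2) = ox; out(r, 3) = oy; out(r, 4) = oz;
      continue;
    }
    int ns = (int)std::ceil(len / step_mm);
    double tprev = 0.0, thit = -1.0;
    for (int s = 1; s <= ns; ++s) {
      double t = std::min(len, s * step_mm);
      double v = trilin(f, dim[0], dim[1], dim[2], sp, org,
                        ox + t * dx, oy + t * dy, oz + t * dz);
      if (v >= thresh) {
        double lo = tprev, hi = t;
        while (hi - lo > tol_mm) {
          double mid = 0.5 * (lo + hi);
          if (trilin(f, dim[0], dim[1], dim[2], sp, org, ox + mid * dx,
                     oy + mid * dy, oz + mid * dz) >= thresh)
            hi = mid;
          else
            lo = mid;
        }
        thit = hi;
        break;
      }
      tprev = t;
    }
    if (thit >= 0) {
      out(r, 0) = 1.0; out(r, 1) = thit;
      out(r, 2) = ox + thit * dx; out(r, 3) = oy + thit * dy;
      out(r, 4) = oz + thit * dz;
    }
  }
  return out;
}

// Labels at uniform samples along one segment (nearest-voxel lookup).
// [[Rcpp::export]]
List cpp_trace(IntegerVector labels, IntegerVector dim, NumericVector spacing,
               NumericVector origin, NumericVector start, NumericVector end,
               double step_mm) {
  double ox = start[0], oy = start[1], oz = start[2];
  double dx = end[0] - ox, dy = end[1] - oy, dz = end[2] - oz;
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  int ns = (len > 0) ? (int)std::ceil(len / step_mm) : 0;
  NumericMatrix pts(ns + 1, 3);
  IntegerVector labs(ns + 1);
  const int* lab = INTEGER(labels);
  for (int s = 0; s <= ns; ++s) {
    double t = (ns == 0) ? 0.0 : std::min(len, s * step_mm);
    double x = ox + (len > 0 ? t * dx / len : 0.0);
    double y = oy + (len > 0 ? t * dy / len : 0.0);
    double z = oz + (len > 0 ? t * dz / len : 0.0);
    pts(s, 0) = x; pts(s, 1) = y; pts(s, 2) = z;
    labs[s] = label_at(lab, dim[0], dim[1], dim[2], REAL(spacing),
                       REAL(origin), x, y, z);
  }
  return List::create(_["points"] = pts, _["labels"] = labs);
}
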