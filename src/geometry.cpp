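// Low-level voxel geometry kernels: exact Euclidean distance transform,
// trilinear interpolation, capsule/sphere rasterisation, segment-mask
// profiling, polyline resampling and 26-connectivity labelling.
// All distances are in world mm; voxel coordinates are 0-based and address
// voxel centres. Affines map 0-based voxel indices to world mm.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---- 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher) --------
// f: input squared distances at positions i*step; d: output; arg: winning
// source position along this axis for feature propagation.
static void dt1d(const std::vector<double>& f, double step,
                 std::vector<double>& d, std::vector<int>& arg) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; arg[q] = q; continue; }
    while (z[k + 1] < q) ++k;
    double dq = step * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// Exact EDT of a binary mask (distance to nearest TRUE voxel), spacing-aware.
// Returns list(distance = mm array, feature = 1-based linear index of a
// nearest TRUE voxel, or NA where the mask is empty).
// [[Rcpp::export(name = ".edt3d_cpp")]]
List edt3d_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing,
               bool feature = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d2(n);
  std::vector<int> feat;
  if (feature) feat.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    d2[i] = mask[i] ? 0.0 : INF;
    if (feature) feat[i] = mask[i] ? (int)i : -1;
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx); std::vector<int> a(nx);
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d2[base + x];
      dt1d(f, spacing[0], d, a);
      std::vector<int> newf;
      if (feature) { newf.resize(nx);
        for (int x = 0; x < nx; ++x) newf[x] = feat[base + a[x]]; }
      for (int x = 0; x < nx; ++x) {
        d2[base + x] = d[x];
        if (feature) feat[base + x] = newf[x];
      }
    }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny); std::vector<int> a(ny);
    for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d2[base + (R_xlen_t)y * nx];
      dt1d(f, spacing[1], d, a);
      std::vector<int> newf;
      if (feature) { newf.resize(ny);
        for (int y = 0; y < ny; ++y) newf[y] = feat[base + (R_xlen_t)a[y] * nx]; }
      for (int y = 0; y < ny; ++y) {
        d2[base + (R_xlen_t)y * nx] = d[y];
        if (feature) feat[base + (R_xlen_t)y * nx] = newf[y];
      }
    }
  }
  // pass along z
  {
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    std::vector<double> f(nz), d(nz); std::vector<int> a(nz);
    for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = d2[base + (R_xlen_t)z * sz];
      dt1d(f, spacing[2], d, a);
      std::vector<int> newf;
      if (feature) { newf.resize(nz);
        for (int z = 0; z < nz; ++z) newf[z] = feat[base + (R_xlen_t)a[z] * sz]; }
      for (int z = 0; z < nz; ++z) {
        d2[base + (R_xlen_t)z * sz] = d[z];
        if (feature) feat[base + (R_xlen_t)z * sz] = newf[z];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(d2[i]) ? R_PosInf : std::sqrt(d2[i]);
  out.attr("dim") = dim;
  List res = List::create(_["distance"] = out);
  if (feature) {
    IntegerVector fv(n);
    for (R_xlen_t i = 0; i < n; ++i)
      fv[i] = feat[i] < 0 ? NA_INTEGER : feat[i] + 1; // 1-based for R
    fv.attr("dim") = dim;
    res["feature"] = fv;
  }
  return res;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of vol at 0-based continuous voxel coords (n x 3).
// Coordinates are clamped to [0, dim-1].
// [[Rcpp::export(name = ".interp3_cpp")]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = clampd(pts(i, 0), 0.0, nx - 1.0);
    double y = clampd(pts(i, 1), 0.0, ny - 1.0);
    double z = clampd(pts(i, 2), 0.0, nz - 1.0);
    int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) { x0 = 0; fx = 0.0; }
    if (ny == 1) { y0 = 0; fy = 0.0; }
    if (nz == 1) { z0 = 0; fz = 0.0; }
    auto V = [&](int a, int b, int c) -> double {
      return vol[(R_xlen_t)c * nx * ny + (R_xlen_t)b * nx + a];
    };
    int x1 = nx == 1 ? 0 : x0 + 1, y1 = ny == 1 ? 0 : y0 + 1,
        z1 = nz == 1 ? 0 : z0 + 1;
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

static inline void apply_affine(const NumericMatrix& A, double i, double j,
                                double k, double* out) {
  for (int r = 0; r < 3; ++r)
    out[r] = A(r, 0) * i + A(r, 1) * j + A(r, 2) * k + A(r, 3);
}

// Squared distance from point p to segment [a, b] in 3D.
static double pt_seg_d2(const double* p, const double* a, const double* b) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = denom > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom
                       : 0.0;
  t = clampd(t, 0.0, 1.0);
  double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
  return dx * dx + dy * dy + dz * dz;
}

// Rasterise capsules: voxel centre set iff within radius of some segment of
// some polyline. polylines: list of (m x 3) world-mm matrices; a 1-row
// polyline rasterises a sphere. affine: voxel->world; inv: world->voxel.
// [[Rcpp::export(name = ".capsule_mask_cpp")]]
LogicalVector capsule_mask_cpp(List polylines, NumericVector radii,
                               IntegerVector dim, NumericMatrix affine,
                               NumericMatrix inv) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dim;
  for (int li = 0; li < polylines.size(); ++li) {
    NumericMatrix P = polylines[li];
    double r = radii[li];
    int nseg = std::max(1, (int)P.nrow() - 1);
    for (int s = 0; s < nseg; ++s) {
      double a[3] = { P(s, 0), P(s, 1), P(s, 2) };
      int s2 = std::min(s + 1, (int)P.nrow() - 1);
      double b[3] = { P(s2, 0), P(s2, 1), P(s2, 2) };
      // world-space bbox of the capsule, mapped through inv at 8 corners
      double lo[3], hi[3];
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(a[c], b[c]) - r;
        hi[c] = std::max(a[c], b[c]) + r;
      }
      double vlo[3] = { INF, INF, INF }, vhi[3] = { -INF, -INF, -INF };
      for (int corner = 0; corner < 8; ++corner) {
        double w[3] = { (corner & 1) ? hi[0] : lo[0],
                        (corner & 2) ? hi[1] : lo[1],
                        (corner & 4) ? hi[2] : lo[2] };
        double v[3];
        apply_affine(inv, w[0], w[1], w[2], v);
        for (int c = 0; c < 3; ++c) {
          vlo[c] = std::min(vlo[c], v[c]);
          vhi[c] = std::max(vhi[c], v[c]);
        }
      }
      int i0 = std::max(0, (int)std::floor(vlo[0]) - 1);
      int j0 = std::max(0, (int)std::floor(vlo[1]) - 1);
      int k0 = std::max(0, (int)std::floor(vlo[2]) - 1);
      int i1 = std::min(nx - 1, (int)std::ceil(vhi[0]) + 1);
      int j1 = std::min(ny - 1, (int)std::ceil(vhi[1]) + 1);
      int k1 = std::min(nz - 1, (int)std::ceil(vhi[2]) + 1);
      double r2 = r * r;
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            double w[3];
            apply_affine(affine, i, j, k, w);
            if (pt_seg_d2(w, a, b) <= r2)
              out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
          }
    }
  }
  return out;
}

// For each row of entry/target (world mm), sample the segment at <= step mm
// and test nearest-voxel membership in mask. Returns per-segment logical.
// [[Rcpp::export(name = ".segments_hit_mask_cpp")]]
LogicalVector segments_hit_mask_cpp(NumericMatrix entry, NumericMatrix target,
                                    LogicalVector mask, IntegerVector dim,
                                    NumericMatrix inv, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = entry.nrow();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double e[3] = { entry(i, 0), entry(i, 1), entry(i, 2) };
    double t[3] = { target(i, 0), target(i, 1), target(i, 2) };
    double L = std::sqrt((t[0]-e[0])*(t[0]-e[0]) + (t[1]-e[1])*(t[1]-e[1]) +
                         (t[2]-e[2])*(t[2]-e[2]));
    int ns = std::max(1, (int)std::ceil(L / step)) + 1;
    bool hit = false;
    for (int s = 0; s < ns && !hit; ++s) {
      double f = (double)s / (ns - 1);
      double w[3] = { e[0] + f * (t[0]-e[0]), e[1] + f * (t[1]-e[1]),
                      e[2] + f * (t[2]-e[2]) };
      double v[3];
      apply_affine(inv, w[0], w[1], w[2], v);
      int a = (int)std::lround(v[0]), b = (int)std::lround(v[1]),
          c = (int)std::lround(v[2]);
      if (a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz) continue;
      if (mask[(R_xlen_t)c * nx * ny + (R_xlen_t)b * nx + a]) hit = true;
    }
    out[i] = hit;
  }
  return out;
}

// Per-segment in-mask profile statistics by <= step mm sampling.
// Columns: nSamples, firstIn, lastIn, nIn, runStart, runEnd (0-based sample
// indices; -1 where no sample is inside). runStart/runEnd delimit the
// longest contiguous in-mask run.
// [[Rcpp::export(name = ".segment_mask_runs_cpp")]]
NumericMatrix segment_mask_runs_cpp(NumericMatrix entry, NumericMatrix target,
                                    LogicalVector mask, IntegerVector dim,
                                    NumericMatrix inv, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = entry.nrow();
  NumericMatrix out(n, 6);
  for (R_xlen_t i = 0; i < n; ++i) {
    double e[3] = { entry(i, 0), entry(i, 1), entry(i, 2) };
    double t[3] = { target(i, 0), target(i, 1), target(i, 2) };
    double L = std::sqrt((t[0]-e[0])*(t[0]-e[0]) + (t[1]-e[1])*(t[1]-e[1]) +
                         (t[2]-e[2])*(t[2]-e[2]));
    int ns = std::max(1, (int)std::ceil(L / step)) + 1;
    int firstIn = -1, lastIn = -1, nIn = 0;
    int bestS = -1, bestE = -1, curS = -1;
    for (int s = 0; s < ns; ++s) {
      double f = ns == 1 ? 0.0 : (double)s / (ns - 1);
      double w[3] = { e[0] + f * (t[0]-e[0]), e[1] + f * (t[1]-e[1]),
                      e[2] + f * (t[2]-e[2]) };
      double v[3];
      apply_affine(inv, w[0], w[1], w[2], v);
      int a = (int)std::lround(v[0]), b = (int)std::lround(v[1]),
          c = (int)std::lround(v[2]);
      bool in = !(a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz) &&
                mask[(R_xlen_t)c * nx * ny + (R_xlen_t)b * nx + a];
      if (in) {
        if (firstIn < 0) firstIn = s;
        lastIn = s; ++nIn;
        if (curS < 0) curS = s;
        if (bestS < 0 || s - curS > bestE - bestS) { bestS = curS; bestE = s; }
      } else {
        curS = -1;
      }
    }
    out(i, 0) = ns; out(i, 1) = firstIn; out(i, 2) = lastIn;
    out(i, 3) = nIn; out(i, 4) = bestS; out(i, 5) = bestE;
  }
  colnames(out) = CharacterVector::create("nSamples", "firstIn", "lastIn",
                                          "nIn", "runStart", "runEnd");
  return out;
}

// Resample a polyline so consecutive points are <= step mm apart; original
// vertices are retained.
// [[Rcpp::export(name = ".resample_polyline_cpp")]]
NumericMatrix resample_polyline_cpp(NumericMatrix P, double step) {
  const int m = P.nrow();
  std::vector<double> pts;
  pts.reserve(3 * m * 2);
  for (int s = 0; s < m - 1; ++s) {
    double a[3] = { P(s, 0), P(s, 1), P(s, 2) };
    double b[3] = { P(s + 1, 0), P(s + 1, 1), P(s + 1, 2) };
    double L = std::sqrt((b[0]-a[0])*(b[0]-a[0]) + (b[1]-a[1])*(b[1]-a[1]) +
                         (b[2]-a[2])*(b[2]-a[2]));
    int k = std::max(1, (int)std::ceil(L / step));
    for (int q = 0; q < k; ++q) {
      double f = (double)q / k;
      pts.push_back(a[0] + f * (b[0]-a[0]));
      pts.push_back(a[1] + f * (b[1]-a[1]));
      pts.push_back(a[2] + f * (b[2]-a[2]));
    }
  }
  pts.push_back(P(m - 1, 0)); pts.push_back(P(m - 1, 1));
  pts.push_back(P(m - 1, 2));
  int nout = (int)pts.size() / 3;
  NumericMatrix out(nout, 3);
  for (int i = 0; i < nout; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = pts[3 * i + c];
  return out;
}

// Unique 1-based linear indices of in-grid voxels traversed by the polyline
// resampled at <= step mm (nearest-voxel membership).
// [[Rcpp::export(name = ".polyline_voxels_cpp")]]
IntegerVector polyline_voxels_cpp(NumericMatrix P, IntegerVector dim,
                                  NumericMatrix inv, double step) {
  NumericMatrix R = resample_polyline_cpp(P, step);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> idx;
  idx.reserve(R.nrow());
  for (int i = 0; i < R.nrow(); ++i) {
    double v[3];
    apply_affine(inv, R(i, 0), R(i, 1), R(i, 2), v);
    int a = (int)std::lround(v[0]), b = (int)std::lround(v[1]),
        c = (int)std::lround(v[2]);
    if (a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz) continue;
    int lin = (int)((R_xlen_t)c * nx * ny + (R_xlen_t)b * nx + a) + 1;
    if (idx.empty() || idx.back() != lin) idx.push_back(lin);
  }
  std::sort(idx.begin(), idx.end());
  idx.erase(std::unique(idx.begin(), idx.end()), idx.end());
  return wrap(idx);
}

// Separable Gaussian smoothing, sigma per axis in voxels, reflected edges.
// [[Rcpp::export(name = ".gauss_smooth3_cpp")]]
NumericVector gauss_smooth3_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int dims[3] = { nx, ny, nz };
  const R_xlen_t strides[3] = { 1, nx, (R_xlen_t)nx * ny };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int i = -rad; i <= rad; ++i) {
      ker[i + rad] = std::exp(-0.5 * i * i / (s * s));
      sum += ker[i + rad];
    }
    for (double& k : ker) k /= sum;
    int m = dims[ax];
    R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    int d1 = (ax + 1) % 3, d2 = (ax + 2) % 3;
    for (int j2 = 0; j2 < dims[d2]; ++j2)
      for (int j1 = 0; j1 < dims[d1]; ++j1) {
        R_xlen_t base = (R_xlen_t)j1 * strides[d1] + (R_xlen_t)j2 * strides[d2];
        for (int i = 0; i < m; ++i) {
          double acc = 0;
          for (int q = -rad; q <= rad; ++q) {
            int p = i + q;
            if (p < 0) p = -p - 1;
            if (p >= m) p = 2 * m - 1 - p;
            acc += ker[q + rad] * a[base + (R_xlen_t)p * st];
          }
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Number of 26-connected components of a binary mask.
// [[Rcpp::export(name = ".n_components26_cpp")]]
int n_components26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  int ncomp = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || seen[i]) continue;
    ++ncomp;
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny),
          z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
            if (mask[q] && !seen[q]) { seen[q] = 1; stack.push_back(q); }
          }
    }
  }
  return ncomp;
}
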