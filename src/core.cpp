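#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 6-connected component labeling of a 3D logical array (column-major,
// dims = c(nx, ny, nz)). Labels 1..K in first-encounter (linear index) order,
// background 0. Iterative flood fill with an explicit stack.
// [[Rcpp::export(name = ".cc_label6")]]
List cc_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int k = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (mask[seed] != TRUE || labels[seed] != 0) continue;
    ++k;
    labels[seed] = k;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int l = (int)(v / sz);
      // six face neighbours
      if (i > 0      && mask[v - sx] == TRUE && labels[v - sx] == 0) { labels[v - sx] = k; stack.push_back(v - sx); }
      if (i < nx - 1 && mask[v + sx] == TRUE && labels[v + sx] == 0) { labels[v + sx] = k; stack.push_back(v + sx); }
      if (j > 0      && mask[v - sy] == TRUE && labels[v - sy] == 0) { labels[v - sy] = k; stack.push_back(v - sy); }
      if (j < ny - 1 && mask[v + sy] == TRUE && labels[v + sy] == 0) { labels[v + sy] = k; stack.push_back(v + sy); }
      if (l > 0      && mask[v - sz] == TRUE && labels[v - sz] == 0) { labels[v - sz] = k; stack.push_back(v - sz); }
      if (l < nz - 1 && mask[v + sz] == TRUE && labels[v + sz] == 0) { labels[v + sz] = k; stack.push_back(v + sz); }
    }
  }
  return List::create(_["labels"] = labels, _["count"] = k);
}

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower-envelope method), with grid step w (physical units).
// f and d have length n; v and z are scratch buffers (n and n+1).
static void dt1d(const double *f, double *d, int n, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  // build the lower envelope over columns with finite f only; infinite
  // parabolas can never contribute to the minimum
  int kk = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (kk < 0) {
      kk = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[kk] && kk > 0) { --kk; } else break;
    }
    if (s <= z[kk]) { // replaced the very first parabola
      v[kk] = q;
      z[kk + 1] = INF;
    } else {
      ++kk;
      v[kk] = q;
      z[kk] = s;
      z[kk + 1] = INF;
    }
  }
  if (kk < 0) { // no finite column
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = (double)(q - v[j]) * w;
    d[q] = dq * dq + f[v[j]];
  }
}

// Exact anisotropic squared Euclidean distance transform: for every voxel,
// the squared physical distance (per-axis steps = spacing, mm) to the centre
// of the nearest voxel where feature == TRUE. Voxels with no feature anywhere
// get Inf.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector feature, IntegerVector dims,
                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (feature[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sz = (R_xlen_t)nx * ny;

  // pass along x
  for (int l = 0; l < nz; ++l)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)l * sz;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int l = 0; l < nz; ++l)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)l * sz;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
      bool any = false;
      for (int l = 0; l < nz; ++l) { f[l] = out[base + (R_xlen_t)l * sz]; if (f[l] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int l = 0; l < nz; ++l) out[base + (R_xlen_t)l * sz] = d[l];
    }
  return out;
}

// For each row of a (n x 3), the squared distance to, and 1-based index of,
// the nearest row of b (m x 3). Exact brute force.
// [[Rcpp::export(name = ".nn_sqdist")]]
List nn_sqdist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector d2(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bj = j; }
    }
    d2[i] = best;
    idx[i] = bj + 1;
  }
  return List::create(_["d2"] = d2, _["idx"] = idx);
}
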