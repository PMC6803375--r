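#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform along a sampled line (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher 2012), sample spacing w.
// f: input squared distances (INF where no site), d: output, both length n.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  const double w2 = w * w;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const double dq = w * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// Anisotropic squared Euclidean distance transform of a 3D array stored
// column-major with dimensions dim = (n1, n2, n3) and physical sample
// spacing (per axis, same order). Returns, for every voxel, the squared
// distance (in physical units) to the nearest voxel where sites is TRUE.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, IntegerVector dim,
                         NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (sites.size() != n) stop("sites length does not match dim");
  NumericVector out(n);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = sites[i] ? 0.0 : INF;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3) {
    for (int i2 = 0; i2 < n2; ++i2) {
      double* line = o + (R_xlen_t)i3 * n1 * n2 + (R_xlen_t)i2 * n1;
      for (int i1 = 0; i1 < n1; ++i1) f[i1] = line[i1];
      dt1d(f, d, n1, spacing[0], v, z);
      for (int i1 = 0; i1 < n1; ++i1) line[i1] = d[i1];
    }
  }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3) {
    for (int i1 = 0; i1 < n1; ++i1) {
      double* base = o + (R_xlen_t)i3 * n1 * n2 + i1;
      for (int i2 = 0; i2 < n2; ++i2) f[i2] = base[(R_xlen_t)i2 * n1];
      dt1d(f, d, n2, spacing[1], v, z);
      for (int i2 = 0; i2 < n2; ++i2) base[(R_xlen_t)i2 * n1] = d[i2];
    }
  }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      double* base = o + (R_xlen_t)i2 * n1 + i1;
      for (int i3 = 0; i3 < n3; ++i3) f[i3] = base[(R_xlen_t)i3 * s3];
      dt1d(f, d, n3, spacing[2], v, z);
      for (int i3 = 0; i3 < n3; ++i3) base[(R_xlen_t)i3 * s3] = d[i3];
    }
  }
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& x : k) x /= s;
  return k;
}

// reflect index into [0, n-1]
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing of a 3D array (column-major, dim as above);
// sigma is given per axis in voxel units, sigma <= 0 skips that axis.
// Boundaries are mirror-reflected.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector x, IntegerVector dim,
                              NumericVector sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (x.size() != n) stop("x length does not match dim");
  NumericVector out = clone(x);
  double* o = REAL(out);
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> buf(nmax), res(nmax);

  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    std::vector<double> k = gauss_kernel(sigma[ax]);
    const int r = ((int)k.size() - 1) / 2;
    int na = (ax == 0) ? n1 : (ax == 1) ? n2 : n3;
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? n1 : (R_xlen_t)n1 * n2;
    // iterate over all lines along axis ax
    int nb = (ax == 0) ? n2 : n1;
    int nc = (ax == 2) ? n2 : n3;
    R_xlen_t sb = (ax == 0) ? n1 : 1;
    R_xlen_t sc = (ax == 2) ? n1 : (R_xlen_t)n1 * n2;
    for (int ic = 0; ic < nc; ++ic) {
      for (int ib = 0; ib < nb; ++ib) {
        double* base = o + ic * sc + ib * sb;
        for (int i = 0; i < na; ++i) buf[i] = base[i * stride];
        for (int i = 0; i < na; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) acc += k[j + r] * buf[refl(i + j, na)];
          res[i] = acc;
        }
        for (int i = 0; i < na; ++i) base[i * stride] = res[i];
      }
    }
  }
  return out;
}

// 6-connected component labeling of a 3D logical array (column-major).
// Labels are assigned in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i1 = (int)(p % n1);
      int i2 = (int)((p / n1) % n2);
      int i3 = (int)(p / s3);
      const R_xlen_t nb[6] = {p - 1, p + 1, p - s2, p + s2, p - s3, p + s3};
      const bool ok[6] = {i1 > 0, i1 < n1 - 1, i2 > 0, i2 < n2 - 1,
                          i3 > 0, i3 < n3 - 1};
      for (int t = 0; t < 6; ++t) {
        if (ok[t] && mask[nb[t]] && lab[nb[t]] == 0) {
          lab[nb[t]] = next;
          stack.push_back(nb[t]);
        }
      }
    }
  }
  return lab;
}
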