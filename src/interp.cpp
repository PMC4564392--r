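#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3-D array sampling at continuous voxel coordinates (0-based), with
// B-spline interpolation of degree 0..4.  Degrees >= 2 require the array to
// be prefiltered (see bspline_prefilter below).  Out-of-field samples are 0.

static inline double get3(const double *a, int d1, int d2, int d3,
                          int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3) return 0.0;
  return a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
}

// centred cardinal B-spline of degree n evaluated at x
static double bspline_val(double x, int n) {
  if (n == 0) return (x >= -0.5 && x < 0.5) ? 1.0 : 0.0;
  // recursion B_n(x) = ((x + (n+1)/2) B_{n-1}(x+1/2) + ((n+1)/2 - x) B_{n-1}(x-1/2)) / n
  double c = (n + 1) / 2.0;
  if (x <= -c || x >= c) return 0.0;
  return ((x + c) * bspline_val(x + 0.5, n - 1) +
          (c - x) * bspline_val(x - 0.5, n - 1)) / n;
}

static inline double sample_trilinear(const double *a, int d1, int d2, int d3,
                                      double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double v = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        if (w > 0) v += w * get3(a, d1, d2, d3, i0 + dx, j0 + dy, k0 + dz);
      }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector arr, IntegerVector dim,
                           NumericMatrix coords, int order) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double *a = arr.begin();
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  if (order == 1) {
    for (R_xlen_t p = 0; p < n; ++p)
      out[p] = sample_trilinear(a, d1, d2, d3, coords(p, 0), coords(p, 1), coords(p, 2));
    return out;
  }
  if (order == 0) {
    for (R_xlen_t p = 0; p < n; ++p) {
      int i = (int)std::floor(coords(p, 0) + 0.5);
      int j = (int)std::floor(coords(p, 1) + 0.5);
      int k = (int)std::floor(coords(p, 2) + 0.5);
      out[p] = get3(a, d1, d2, d3, i, j, k);
    }
    return out;
  }
  // degree 2..4 tensor-product B-spline on prefiltered coefficients
  int supp = order + 1;
  std::vector<double> wx(supp), wy(supp), wz(supp);
  std::vector<int> ix(supp), iy(supp), iz(supp);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    int bx = (int)std::ceil(x - (order + 1) / 2.0);
    int by = (int)std::ceil(y - (order + 1) / 2.0);
    int bz = (int)std::ceil(z - (order + 1) / 2.0);
    if (order == 3) {           // closed-form cubic weights (hot path)
      double u = x - std::floor(x);
      bx = (int)std::floor(x) - 1;
      wx[0] = (1 - u) * (1 - u) * (1 - u) / 6.0;
      wx[1] = (4 - 6 * u * u + 3 * u * u * u) / 6.0;
      wx[2] = (1 + 3 * u + 3 * u * u - 3 * u * u * u) / 6.0;
      wx[3] = u * u * u / 6.0;
      u = y - std::floor(y); by = (int)std::floor(y) - 1;
      wy[0] = (1 - u) * (1 - u) * (1 - u) / 6.0;
      wy[1] = (4 - 6 * u * u + 3 * u * u * u) / 6.0;
      wy[2] = (1 + 3 * u + 3 * u * u - 3 * u * u * u) / 6.0;
      wy[3] = u * u * u / 6.0;
      u = z - std::floor(z); bz = (int)std::floor(z) - 1;
      wz[0] = (1 - u) * (1 - u) * (1 - u) / 6.0;
      wz[1] = (4 - 6 * u * u + 3 * u * u * u) / 6.0;
      wz[2] = (1 + 3 * u + 3 * u * u - 3 * u * u * u) / 6.0;
      wz[3] = u * u * u / 6.0;
      for (int s = 0; s < supp; ++s) { ix[s] = bx + s; iy[s] = by + s; iz[s] = bz + s; }
      // interior fast path: no per-fetch bounds checks
      if (bx >= 0 && by >= 0 && bz >= 0 &&
          bx + 3 < d1 && by + 3 < d2 && bz + 3 < d3) {
        double v = 0.0;
        const double *base = a + bx + (R_xlen_t)d1 * (by + (R_xlen_t)d2 * bz);
        for (int c = 0; c < 4; ++c) {
          const double *pz = base + (R_xlen_t)d1 * d2 * c;
          double vz = 0.0;
          for (int b = 0; b < 4; ++b) {
            const double *py = pz + (R_xlen_t)d1 * b;
            vz += wy[b] * (wx[0] * py[0] + wx[1] * py[1] +
                           wx[2] * py[2] + wx[3] * py[3]);
          }
          v += wz[c] * vz;
        }
        out[p] = v;
        continue;
      }
    } else {
      for (int s = 0; s < supp; ++s) {
        ix[s] = bx + s; wx[s] = bspline_val(x - ix[s], order);
        iy[s] = by + s; wy[s] = bspline_val(y - iy[s], order);
        iz[s] = bz + s; wz[s] = bspline_val(z - iz[s], order);
      }
    }
    double v = 0.0;
    for (int c = 0; c < supp; ++c) {
      if (wz[c] == 0) continue;
      for (int b = 0; b < supp; ++b) {
        if (wy[b] == 0) continue;
        double wyz = wy[b] * wz[c];
        for (int s = 0; s < supp; ++s)
          if (wx[s] != 0)
            v += wx[s] * wyz * get3(a, d1, d2, d3, ix[s], iy[b], iz[c]);
      }
    }
    out[p] = v;
  }
  return out;
}

// causal/anticausal IIR prefilter along one line (mirror boundary)
static void filter_line(double *c, int n, const double *poles, int npoles) {
  if (n < 2) return;
  double lambda = 1.0;
  for (int p = 0; p < npoles; ++p)
    lambda *= (1.0 - poles[p]) * (1.0 - 1.0 / poles[p]);
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  for (int p = 0; p < npoles; ++p) {
    double z = poles[p];
    // causal init (mirror): sum z^i c[i]
    double sum = c[0];
    double zn = z;
    int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
    if (horizon > 2 * n - 2) horizon = 2 * n - 2;
    for (int i = 1; i <= horizon; ++i) {
      int idx = i < n ? i : 2 * n - 2 - i;   // mirror index
      sum += zn * c[idx];
      zn *= z;
    }
    c[0] = sum;
    for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
    // anticausal init
    c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
    for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr, IntegerVector dim, int order) {
  NumericVector out = clone(arr);
  if (order < 2) return out;
  double poles4[2] = {std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0,
                      std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0};
  double pole2 = std::sqrt(8.0) - 3.0;
  double pole3 = std::sqrt(3.0) - 2.0;
  const double *poles; int npoles;
  if (order == 2)      { poles = &pole2;    npoles = 1; }
  else if (order == 3) { poles = &pole3;    npoles = 1; }
  else                 { poles = poles4;    npoles = 2; }
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  double *a = out.begin();
  std::vector<double> line(std::max(d1, std::max(d2, d3)));
  // axis 1
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      double *base = a + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      filter_line(base, d1, poles, npoles);
    }
  // axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      for (int j = 0; j < d2; ++j) line[j] = a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
      filter_line(line.data(), d2, poles, npoles);
      for (int j = 0; j < d2; ++j) a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = line[j];
    }
  // axis 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      for (int k = 0; k < d3; ++k) line[k] = a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
      filter_line(line.data(), d3, poles, npoles);
      for (int k = 0; k < d3; ++k) a[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = line[k];
    }
  return out;
}
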