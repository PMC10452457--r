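#include <Rcpp.h>
#include <vector>

// Exact Euclidean distance transform on a regular anisotropic grid:
// separable lower-envelope-of-parabolas algorithm (Felzenszwalb &
// Huttenlocher), one pass per image dimension.  Distances are between voxel
// CENTERS, in physical units given by `spacing`.

static const double BIG = 1e15;  // stand-in for +Inf; true sq. distances << BIG

// 1D squared-distance transform, samples at x_i = i*s.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double fq = f[q] + xq * xq;
    while (true) {
      double xv = v[k] * s;
      double inter = (fq - (f[v[k]] + xv * xv)) / (2.0 * s * (q - v[k]));
      if (inter <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
Rcpp::NumericVector edt_sq_cpp(Rcpp::LogicalVector feature,
                               Rcpp::IntegerVector dims,
                               Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (feature[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index, stride 1)
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy) {
      R_xlen_t off = (R_xlen_t)kz * nx * ny + (R_xlen_t)jy * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[off + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[off + i] = d[i];
    }
  // pass along y (stride nx)
  for (int kz = 0; kz < nz; ++kz)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t off = (R_xlen_t)kz * nx * ny + ix;
      for (int j = 0; j < ny; ++j) f[j] = out[off + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[off + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int jy = 0; jy < ny; ++jy)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t off = (R_xlen_t)jy * nx + ix;
      for (int k2 = 0; k2 < nz; ++k2) f[k2] = out[off + (R_xlen_t)k2 * sxy];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k2 = 0; k2 < nz; ++k2) out[off + (R_xlen_t)k2 * sxy] = d[k2];
    }
  return out;
}
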