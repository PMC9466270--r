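#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// sample positions x_i = i * w where w is the voxel spacing along the axis.
// f holds squared distances from previous passes; result overwrites d.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * q * w * w) - (f[p] + p * p * w * w)) /
          (2.0 * w * (q - p));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q * w) k++;
    double dx = (q - v[k]) * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nx * ny] = std::sqrt(d[z]);
    }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution. sigma is in voxels, per axis; sigma <= 0
// skips the axis. Zero boundary condition (renorm = false) keeps the operator
// symmetric (self-adjoint), which the plan optimizer relies on; renorm = true
// renormalizes the kernel over the in-bounds support (no edge darkening).
// ---------------------------------------------------------------------------
static void conv1d_axis(std::vector<double> &vals, int nx, int ny, int nz,
                        int axis, double sigma, bool renorm) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; i++) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;

  int nAxis = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  std::vector<double> line(nAxis), res(nAxis);

  int nOut1 = axis == 0 ? ny : nx;
  int nOut2 = axis == 2 ? ny : nz;
  R_xlen_t st1 = axis == 0 ? nx : 1;
  R_xlen_t st2 = axis == 2 ? nx : (R_xlen_t)nx * ny;

  for (int b = 0; b < nOut2; b++)
    for (int a = 0; a < nOut1; a++) {
      R_xlen_t base = a * st1 + b * st2;
      for (int i = 0; i < nAxis; i++) line[i] = vals[base + i * stride];
      for (int i = 0; i < nAxis; i++) {
        double acc = 0, wsum = 0;
        int lo = std::max(0, i - radius), hi = std::min(nAxis - 1, i + radius);
        for (int j = lo; j <= hi; j++) {
          double w = k[j - i + radius];
          acc += w * line[j];
          wsum += w;
        }
        res[i] = renorm ? (wsum > 0 ? acc / wsum : 0.0) : acc;
      }
      for (int i = 0; i < nAxis; i++) vals[base + i * stride] = res[i];
    }
}

// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dims,
                          NumericVector sigmaVox, bool renorm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> vals(n);
  for (R_xlen_t i = 0; i < n; i++) vals[i] = arr[i];
  conv1d_axis(vals, nx, ny, nz, 0, sigmaVox[0], renorm);
  conv1d_axis(vals, nx, ny, nz, 1, sigmaVox[1], renorm);
  conv1d_axis(vals, nx, ny, nz, 2, sigmaVox[2], renorm);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = vals[i];
  return out;
}

// ---------------------------------------------------------------------------
// 3-D bilateral filter: weights Gaussian in physical distance (sigma given in
// voxels per axis) and in intensity difference (rangeSd, intensity units).
// NaN neighbours are skipped; a NaN centre voxel stays NaN.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_bilateral3d")]]
NumericVector cpp_bilateral3d(NumericVector arr, IntegerVector dims,
                              NumericVector sigmaVox, double rangeSd) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // truncation at 3.5 sd, matching the separable Gaussian filter
  int rx = std::max(1, (int)std::ceil(3.5 * sigmaVox[0]));
  int ry = std::max(1, (int)std::ceil(3.5 * sigmaVox[1]));
  int rz = std::max(1, (int)std::ceil(3.5 * sigmaVox[2]));
  // precompute spatial kernel
  std::vector<double> kx(2 * rx + 1), ky(2 * ry + 1), kz(2 * rz + 1);
  for (int i = -rx; i <= rx; i++)
    kx[i + rx] = std::exp(-0.5 * i * i / (sigmaVox[0] * sigmaVox[0]));
  for (int i = -ry; i <= ry; i++)
    ky[i + ry] = std::exp(-0.5 * i * i / (sigmaVox[1] * sigmaVox[1]));
  for (int i = -rz; i <= rz; i++)
    kz[i + rz] = std::exp(-0.5 * i * i / (sigmaVox[2] * sigmaVox[2]));
  double inv2r2 = 1.0 / (2.0 * rangeSd * rangeSd);

  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        double c = arr[idx];
        if (ISNAN(c)) { out[idx] = NA_REAL; continue; }
        double acc = 0, wsum = 0;
        int zlo = std::max(0, z - rz), zhi = std::min(nz - 1, z + rz);
        int ylo = std::max(0, y - ry), yhi = std::min(ny - 1, y + ry);
        int xlo = std::max(0, x - rx), xhi = std::min(nx - 1, x + rx);
        for (int zz = zlo; zz <= zhi; zz++)
          for (int yy = ylo; yy <= yhi; yy++) {
            double kzy = kz[zz - z + rz] * ky[yy - y + ry];
            R_xlen_t rowBase = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
            for (int xx = xlo; xx <= xhi; xx++) {
              double v = arr[rowBase + xx];
              if (ISNAN(v)) continue;
              double dv = v - c;
              double w = kzy * kx[xx - x + rx] * std::exp(-dv * dv * inv2r2);
              acc += w * v;
              wsum += w;
            }
          }
        out[idx] = wsum > 0 ? acc / wsum : c;
      }
  return out;
}
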