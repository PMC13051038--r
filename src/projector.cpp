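#include <Rcpp.h>
using namespace Rcpp;

// Plane-wise separable convolution core of the rotation-based projector.
//
// The source volume is an (nx, ny, nz) array in R's column-major order,
// already rotated so that the detector lies along +y; plane j is the
// (x, z) slab at y-index j.  Planes are grouped by quantized PSF distance
// (grp: 1-based group id per plane, equal ids share one kernel); the
// forward pass sums each group's planes, convolves the sum once with the
// group's separable kernel (kx along x, kz along z) and accumulates into
// one (nx, nz) projection.  The adjoint convolves the projection once per
// group and spreads it into every member plane.  Kernels are odd-length
// and symmetric, so convolution is self-adjoint and the R-level
// forward/back pair is an exact transpose.

static void conv1d_cols(const double* in, double* out, int n, int m,
                        const double* k, int klen) {
  // convolve each length-n column of an n x m matrix with k (zero padded)
  int h = (klen - 1) / 2;
  for (int c = 0; c < m; ++c) {
    const double* col = in + (size_t)c * n;
    double* oc = out + (size_t)c * n;
    int lo_end = std::min(h, n);
    for (int i = 0; i < lo_end; ++i) {
      double acc = 0.0;
      int u1 = std::min(n - 1, i + h);
      for (int u = 0; u <= u1; ++u) acc += k[i - u + h] * col[u];
      oc[i] = acc;
    }
    for (int i = h; i < n - h; ++i) {  // interior: no bounds checks
      double acc = 0.0;
      const double* c0 = col + i - h;
      for (int u = 0; u < klen; ++u) acc += k[klen - 1 - u] * c0[u];
      oc[i] = acc;
    }
    for (int i = std::max(h, n - h); i < n; ++i) {
      double acc = 0.0;
      int u0 = std::max(0, i - h);
      for (int u = u0; u < n; ++u) acc += k[i - u + h] * col[u];
      oc[i] = acc;
    }
  }
}

static void conv1d_rows(const double* in, double* out, int n, int m,
                        const double* k, int klen) {
  // convolve each length-m row of an n x m matrix with k (zero padded)
  int h = (klen - 1) / 2;
  for (int j = 0; j < m; ++j) {
    int v0 = std::max(0, j - h), v1 = std::min(m - 1, j + h);
    double* oc = out + (size_t)j * n;
    for (int i = 0; i < n; ++i) oc[i] = 0.0;
    for (int v = v0; v <= v1; ++v) {
      double w = k[j - v + h];
      const double* ic = in + (size_t)v * n;
      for (int i = 0; i < n; ++i) oc[i] += w * ic[i];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_fwd_planes(NumericVector vol, IntegerVector dims,
                             IntegerVector grp, List kx, List kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ngrp = kx.size();
  NumericMatrix P(nx, nz);
  std::vector<double> plane((size_t)nx * nz), tmp((size_t)nx * nz);
  const double* v = vol.begin();
  int j = 0;
  for (int g = 0; g < ngrp; ++g) {
    std::fill(plane.begin(), plane.end(), 0.0);
    for (; j < ny && grp[j] == g + 1; ++j) {
      for (int k = 0; k < nz; ++k) {
        const double* src = v + (size_t)j * nx + (size_t)k * nx * ny;
        double* dst = plane.data() + (size_t)k * nx;
        for (int i = 0; i < nx; ++i) dst[i] += src[i];
      }
    }
    NumericVector kxg = kx[g], kzg = kz[g];
    if (kxg.size() == 1 && kzg.size() == 1) {
      double s = kxg[0] * kzg[0];
      for (size_t t = 0; t < plane.size(); ++t) P[t] += s * plane[t];
    } else {
      conv1d_cols(plane.data(), tmp.data(), nx, nz, kxg.begin(), kxg.size());
      conv1d_rows(tmp.data(), plane.data(), nx, nz, kzg.begin(), kzg.size());
      for (size_t t = 0; t < plane.size(); ++t) P[t] += plane[t];
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_adj_planes(NumericMatrix P, IntegerVector dims,
                             IntegerVector grp, List kx, List kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ngrp = kx.size();
  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> plane((size_t)nx * nz), tmp((size_t)nx * nz);
  double* o = out.begin();
  int j = 0;
  for (int g = 0; g < ngrp; ++g) {
    NumericVector kxg = kx[g], kzg = kz[g];
    if (kxg.size() == 1 && kzg.size() == 1) {
      double s = kxg[0] * kzg[0];
      for (size_t t = 0; t < plane.size(); ++t) plane[t] = s * P[t];
    } else {
      conv1d_cols(&P[0], tmp.data(), nx, nz, kxg.begin(), kxg.size());
      conv1d_rows(tmp.data(), plane.data(), nx, nz, kzg.begin(), kzg.size());
    }
    for (; j < ny && grp[j] == g + 1; ++j) {
      for (int k = 0; k < nz; ++k) {
        double* dst = o + (size_t)j * nx + (size_t)k * nx * ny;
        const double* src = plane.data() + (size_t)k * nx;
        for (int i = 0; i < nx; ++i) dst[i] = src[i];
      }
    }
  }
  return out;
}
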