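#include <Rcpp.h>
using namespace Rcpp;

// Rigid-body resampling of a 3D volume on its own grid.
//
// For every output voxel p (0-based continuous coordinates), the source
// location is  q = Rinv * (p - c - t) + c  where c is the grid center and t
// the translation in voxels; the forward map is p = R*(q - c) + c + t.
// Samples outside the input extent are zero; interpolated values are clipped
// at zero because MR magnitudes are nonnegative.
//
// q is affine in the output indices, so the inner loop advances the source
// coordinates incrementally and uses an unchecked 8-corner gather whenever
// the whole trilinear support is interior.
//
// interp: 0 = nearest neighbour, 1 = trilinear.

static inline double sample_nearest(const double *v, int nx, int ny, int nz,
                                    double qx, double qy, double qz) {
  const int xi = (int)std::lround(qx);
  const int yi = (int)std::lround(qy);
  const int zi = (int)std::lround(qz);
  if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
    return 0.0;
  const double val = v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
  return val > 0.0 ? val : 0.0;
}

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double qx, double qy, double qz) {
  const double fx = std::floor(qx), fy = std::floor(qy), fz = std::floor(qz);
  const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
  if (x0 < -1 || x0 >= nx || y0 < -1 || y0 >= ny || z0 < -1 || z0 >= nz)
    return 0.0;
  const double wx = qx - fx, wy = qy - fy, wz = qz - fz;
  if (x0 >= 0 && x0 < nx - 1 && y0 >= 0 && y0 < ny - 1 &&
      z0 >= 0 && z0 < nz - 1) {
    const double *b = v + x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    const double c00 = b[0] + wx * (b[1] - b[0]);
    const double c10 = b[sy] + wx * (b[sy + 1] - b[sy]);
    const double c01 = b[sz] + wx * (b[sz + 1] - b[sz]);
    const double c11 = b[sz + sy] + wx * (b[sz + sy + 1] - b[sz + sy]);
    const double c0 = c00 + wy * (c10 - c00);
    const double c1 = c01 + wy * (c11 - c01);
    const double acc = c0 + wz * (c1 - c0);
    return acc > 0.0 ? acc : 0.0;
  }
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    const int z = z0 + dz;
    if (z < 0 || z >= nz) continue;
    const double wwz = dz ? wz : 1.0 - wz;
    if (wwz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      const int y = y0 + dy;
      if (y < 0 || y >= ny) continue;
      const double wwy = dy ? wy : 1.0 - wy;
      if (wwy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        const int x = x0 + dx;
        if (x < 0 || x >= nx) continue;
        const double wwx = dx ? wx : 1.0 - wx;
        if (wwx == 0.0) continue;
        acc += wwz * wwy * wwx * v[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      }
    }
  }
  return acc > 0.0 ? acc : 0.0;
}

static void resample_plane(const double *v, double *o, const int *dims,
                           const double *rinv, const double *trans,
                           int k, int interp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double pz = k - cz - trans[2];
  for (int j = 0; j < ny; ++j) {
    const double py = j - cy - trans[1];
    const double px0 = -cx - trans[0];
    // affine in i: advance by the first column of Rinv
    double qx = rinv[0] * px0 + rinv[3] * py + rinv[6] * pz + cx;
    double qy = rinv[1] * px0 + rinv[4] * py + rinv[7] * pz + cy;
    double qz = rinv[2] * px0 + rinv[5] * py + rinv[8] * pz + cz;
    double *orow = o + (R_xlen_t)nx * j;
    if (interp == 0) {
      for (int i = 0; i < nx; ++i) {
        orow[i] = sample_nearest(v, nx, ny, nz, qx, qy, qz);
        qx += rinv[0]; qy += rinv[1]; qz += rinv[2];
      }
    } else {
      for (int i = 0; i < nx; ++i) {
        orow[i] = sample_trilinear(v, nx, ny, nz, qx, qy, qz);
        qx += rinv[0]; qy += rinv[1]; qz += rinv[2];
      }
    }
  }
}

// [[Rcpp::export(name = ".resample_rigid_cpp")]]
NumericVector resample_rigid_cpp(NumericVector vol, IntegerVector dims,
                                 NumericMatrix Rinv, NumericVector trans,
                                 int interp) {
  NumericVector out((R_xlen_t)dims[0] * dims[1] * dims[2]);
  for (int k = 0; k < dims[2]; ++k) {
    resample_plane(vol.begin(), out.begin() + (R_xlen_t)dims[0] * dims[1] * k,
                   dims.begin(), Rinv.begin(), trans.begin(), k, interp);
  }
  out.attr("dim") = dims;
  return out;
}

// Resample only output slice z (0-based) of the transformed volume: the
// k-space composition of one slice needs just that plane of each state.

// [[Rcpp::export(name = ".resample_rigid_slice_cpp")]]
NumericMatrix resample_rigid_slice_cpp(NumericVector vol, IntegerVector dims,
                                       NumericMatrix Rinv,
                                       NumericVector trans, int z,
                                       int interp) {
  NumericMatrix out(dims[0], dims[1]);
  resample_plane(vol.begin(), out.begin(), dims.begin(), Rinv.begin(),
                 trans.begin(), z, interp);
  return out;
}
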