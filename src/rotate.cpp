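#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3D volume under a rigid transform.
// Output voxel at 0-based index x gets the input value at
//   q = Rinv * (x - c - shift) + c
// where c = floor(dim/2) is the rotation centre (FFT-consistent).
// Out-of-bounds samples are zero.
// [[Rcpp::export]]
NumericVector rotate_trilinear(NumericVector vol, IntegerVector dims,
                               NumericMatrix Rinv, NumericVector shift) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = nx / 2, cy = ny / 2, cz = nz / 2;
  NumericVector out(nx * ny * nz);
  const double r11 = Rinv(0,0), r12 = Rinv(0,1), r13 = Rinv(0,2);
  const double r21 = Rinv(1,0), r22 = Rinv(1,1), r23 = Rinv(1,2);
  const double r31 = Rinv(2,0), r32 = Rinv(2,1), r33 = Rinv(2,2);
  const double sx = shift[0], sy = shift[1], sz = shift[2];
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < nz; ++k) {
    const double pz = k - cz - sz;
    for (int j = 0; j < ny; ++j) {
      const double py = j - cy - sy;
      for (int i = 0; i < nx; ++i) {
        const double px = i - cx - sx;
        const double qx = r11 * px + r12 * py + r13 * pz + cx;
        const double qy = r21 * px + r22 * py + r23 * pz + cy;
        const double qz = r31 * px + r32 * py + r33 * pz + cz;
        int x0 = (int)std::floor(qx);
        int y0 = (int)std::floor(qy);
        int z0 = (int)std::floor(qz);
        // a sample landing exactly on the far face is still in bounds
        if (x0 == nx - 1 && qx <= nx - 1 + 1e-9) x0 = nx - 2;
        if (y0 == ny - 1 && qy <= ny - 1 + 1e-9) y0 = ny - 2;
        if (z0 == nz - 1 && qz <= nz - 1 + 1e-9) z0 = nz - 2;
        if (x0 < 0 || y0 < 0 || z0 < 0 ||
            x0 >= nx - 1 || y0 >= ny - 1 || z0 >= nz - 1) {
          o[i + nx * (j + (long)ny * k)] = 0.0;
          continue;
        }
        const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
        const long b = x0 + nx * (y0 + (long)ny * z0);
        const long dz = (long)nx * ny;
        const double c00 = v[b] * (1 - fx) + v[b + 1] * fx;
        const double c10 = v[b + nx] * (1 - fx) + v[b + nx + 1] * fx;
        const double c01 = v[b + dz] * (1 - fx) + v[b + dz + 1] * fx;
        const double c11 = v[b + dz + nx] * (1 - fx) + v[b + dz + nx + 1] * fx;
        const double c0 = c00 * (1 - fy) + c10 * fy;
        const double c1 = c01 * (1 - fy) + c11 * fy;
        o[i + nx * (j + (long)ny * k)] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}
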