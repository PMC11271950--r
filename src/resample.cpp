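#include <Rcpp.h>
using namespace Rcpp;

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1)
static inline void cubic_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline double at(const double* v, int nx, int ny, int nz,
                        int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

// Resample a 3D array on an affine grid: output voxel (i,j,k) (0-based) takes
// the value of the input at continuous 0-based voxel coordinates
// p = A %*% c(i,j,k,1). interp: 0 = trilinear, 1 = cubic (Catmull-Rom).
// Out-of-field samples are 0.
// [[Rcpp::export]]
NumericVector resample_affine(NumericVector vol, IntegerVector dims,
                              NumericMatrix A, int interp) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vol.begin();
  NumericVector outv((size_t)nx * ny * nz);
  double* o = outv.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2), a03 = A(0,3);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2), a13 = A(1,3);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2), a23 = A(2,3);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      double xb = a01 * j + a02 * k + a03;
      double yb = a11 * j + a12 * k + a13;
      double zb = a21 * j + a22 * k + a23;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = a00 * i + xb, y = a10 * i + yb, z = a20 * i + zb;
        if (interp == 0) {
          double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
          int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          if (i0 < -1 || j0 < -1 || k0 < -1 ||
              i0 > nx - 1 || j0 > ny - 1 || k0 > nz - 1) { o[idx] = 0.0; continue; }
          double tx = x - fx, ty = y - fy, tz = z - fz;
          double c00 = at(v,nx,ny,nz,i0,j0,k0)   * (1-tx) + at(v,nx,ny,nz,i0+1,j0,k0)   * tx;
          double c10 = at(v,nx,ny,nz,i0,j0+1,k0) * (1-tx) + at(v,nx,ny,nz,i0+1,j0+1,k0) * tx;
          double c01 = at(v,nx,ny,nz,i0,j0,k0+1)   * (1-tx) + at(v,nx,ny,nz,i0+1,j0,k0+1)   * tx;
          double c11 = at(v,nx,ny,nz,i0,j0+1,k0+1) * (1-tx) + at(v,nx,ny,nz,i0+1,j0+1,k0+1) * tx;
          o[idx] = (c00 * (1-ty) + c10 * ty) * (1-tz) + (c01 * (1-ty) + c11 * ty) * tz;
        } else {
          double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
          int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          if (i0 < -2 || j0 < -2 || k0 < -2 ||
              i0 > nx || j0 > ny || k0 > nz) { o[idx] = 0.0; continue; }
          double wx[4], wy[4], wz[4];
          cubic_weights(x - fx, wx);
          cubic_weights(y - fy, wy);
          cubic_weights(z - fz, wz);
          double acc = 0.0;
          for (int c = 0; c < 4; ++c) {
            double accy = 0.0;
            for (int b = 0; b < 4; ++b) {
              double accx = 0.0;
              for (int a = 0; a < 4; ++a)
                accx += wx[a] * at(v, nx, ny, nz, i0 - 1 + a, j0 - 1 + b, k0 - 1 + c);
              accy += wy[b] * accx;
            }
            acc += wz[c] * accy;
          }
          o[idx] = acc;
        }
      }
    }
  }
  outv.attr("dim") = dims;
  return outv;
}
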