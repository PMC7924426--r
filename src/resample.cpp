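// Volume resampling under an affine index map.
// Output voxel (i,j,k) (0-based) samples the input at p = A * (i,j,k)' + t,
// in 0-based input voxel coordinates.  order: 0 nearest, 1 trilinear,
// 3 tricubic (Keys kernel, a = -0.5).  boundary: "clamp" clamps the sample
// point to the grid; "zero" fills samples whose centre falls outside.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double keys_w(double d, double a) {
  d = std::fabs(d);
  if (d <= 1.0) return (a + 2.0) * d * d * d - (a + 3.0) * d * d + 1.0;
  if (d < 2.0)  return a * d * d * d - 5.0 * a * d * d + 8.0 * a * d - 4.0 * a;
  return 0.0;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export(name = ".resampleAffineCpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector in_dim,
                                  NumericMatrix A, NumericVector t,
                                  IntegerVector out_dim, int order,
                                  double fill, bool clamp_boundary) {
  const int n1 = in_dim[0], n2 = in_dim[1], n3 = in_dim[2];
  const int m1 = out_dim[0], m2 = out_dim[1], m3 = out_dim[2];
  const double *v = vol.begin();
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  out.attr("dim") = out_dim;
  double *o = out.begin();
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  const double t0 = t[0], t1 = t[1], t2 = t[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  R_xlen_t idx = 0;
  for (int k = 0; k < m3; ++k) {
    for (int j = 0; j < m2; ++j) {
      for (int i = 0; i < m1; ++i, ++idx) {
        double px = a00 * i + a01 * j + a02 * k + t0;
        double py = a10 * i + a11 * j + a12 * k + t1;
        double pz = a20 * i + a21 * j + a22 * k + t2;
        if (clamp_boundary) {
          px = std::min(std::max(px, 0.0), (double)(n1 - 1));
          py = std::min(std::max(py, 0.0), (double)(n2 - 1));
          pz = std::min(std::max(pz, 0.0), (double)(n3 - 1));
        } else if (px < 0.0 || px > n1 - 1 || py < 0.0 || py > n2 - 1 ||
                   pz < 0.0 || pz > n3 - 1) {
          o[idx] = fill;
          continue;
        }
        if (order == 0) {
          int ix = clampi((int)std::llround(px), 0, n1 - 1);
          int iy = clampi((int)std::llround(py), 0, n2 - 1);
          int iz = clampi((int)std::llround(pz), 0, n3 - 1);
          o[idx] = v[ix + s2 * iy + s3 * iz];
        } else if (order == 1) {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          int x1 = clampi(x0 + 1, 0, n1 - 1), y1 = clampi(y0 + 1, 0, n2 - 1),
              z1 = clampi(z0 + 1, 0, n3 - 1);
          x0 = clampi(x0, 0, n1 - 1); y0 = clampi(y0, 0, n2 - 1);
          z0 = clampi(z0, 0, n3 - 1);
          double c00 = v[x0 + s2*y0 + s3*z0] * (1-fx) + v[x1 + s2*y0 + s3*z0] * fx;
          double c10 = v[x0 + s2*y1 + s3*z0] * (1-fx) + v[x1 + s2*y1 + s3*z0] * fx;
          double c01 = v[x0 + s2*y0 + s3*z1] * (1-fx) + v[x1 + s2*y0 + s3*z1] * fx;
          double c11 = v[x0 + s2*y1 + s3*z1] * (1-fx) + v[x1 + s2*y1 + s3*z1] * fx;
          double c0 = c00 * (1-fy) + c10 * fy;
          double c1 = c01 * (1-fy) + c11 * fy;
          o[idx] = c0 * (1-fz) + c1 * fz;
        } else {
          const double a = -0.5;
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double wx[4], wy[4], wz[4];
          int xi[4], yi[4], zi[4];
          for (int u = 0; u < 4; ++u) {
            int off = u - 1;
            wx[u] = keys_w(px - (x0 + off), a);
            wy[u] = keys_w(py - (y0 + off), a);
            wz[u] = keys_w(pz - (z0 + off), a);
            xi[u] = clampi(x0 + off, 0, n1 - 1);
            yi[u] = clampi(y0 + off, 0, n2 - 1);
            zi[u] = clampi(z0 + off, 0, n3 - 1);
          }
          double acc = 0.0;
          for (int w = 0; w < 4; ++w) {
            if (wz[w] == 0.0) continue;
            double accy = 0.0;
            for (int u = 0; u < 4; ++u) {
              if (wy[u] == 0.0) continue;
              const double *row = v + s2 * yi[u] + s3 * zi[w];
              double accx = wx[0] * row[xi[0]] + wx[1] * row[xi[1]] +
                            wx[2] * row[xi[2]] + wx[3] * row[xi[3]];
              accy += wy[u] * accx;
            }
            acc += wz[w] * accy;
          }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Nearest-neighbour sampling of a volume at arbitrary 0-based coordinates
// (used by the oblique slicer); points outside the grid get `fill`.
// [[Rcpp::export(name = ".sampleNearestCpp")]]
NumericVector sample_nearest_cpp(NumericVector vol, IntegerVector in_dim,
                                 NumericMatrix pts, double fill) {
  const int n1 = in_dim[0], n2 = in_dim[1], n3 = in_dim[2];
  const double *v = vol.begin();
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    if (px < -0.5 || px > n1 - 0.5 || py < -0.5 || py > n2 - 0.5 ||
        pz < -0.5 || pz > n3 - 0.5) {
      out[p] = fill;
      continue;
    }
    int ix = clampi((int)std::llround(px), 0, n1 - 1);
    int iy = clampi((int)std::llround(py), 0, n2 - 1);
    int iz = clampi((int)std::llround(pz), 0, n3 - 1);
    out[p] = v[ix + s2 * iy + s3 * iz];
  }
  return out;
}
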