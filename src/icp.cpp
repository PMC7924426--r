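// Point-to-point iterative closest point with a uniform-grid nearest
// neighbour index and closed-form rigid updates (cross-covariance SVD with
// determinant correction).  Each iteration re-fits the global transform from
// the original source to the current correspondences, so the returned (R, t)
// is the composite transform mapping source into the target frame.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GridIndex {
  arma::mat pts;           // 3 x M
  double cell;
  arma::vec lo;
  int nx, ny, nz;
  std::vector< std::vector<int> > cells;

  GridIndex(const arma::mat &p, double cell_size) : pts(p), cell(cell_size) {
    lo = arma::min(pts, 1);
    arma::vec hi = arma::max(pts, 1);
    nx = (int)std::floor((hi[0] - lo[0]) / cell) + 1;
    ny = (int)std::floor((hi[1] - lo[1]) / cell) + 1;
    nz = (int)std::floor((hi[2] - lo[2]) / cell) + 1;
    // keep the table bounded for pathological spreads
    while ((double)nx * ny * nz > 2e7) {
      cell *= 2.0;
      nx = (int)std::floor((hi[0] - lo[0]) / cell) + 1;
      ny = (int)std::floor((hi[1] - lo[1]) / cell) + 1;
      nz = (int)std::floor((hi[2] - lo[2]) / cell) + 1;
    }
    cells.resize((size_t)nx * ny * nz);
    for (arma::uword m = 0; m < pts.n_cols; ++m)
      cells[cell_of(pts(0, m), pts(1, m), pts(2, m))].push_back((int)m);
  }

  inline int clampc(int v, int n) const { return v < 0 ? 0 : (v >= n ? n - 1 : v); }

  inline size_t cell_of(double x, double y, double z) const {
    int cx = clampc((int)std::floor((x - lo[0]) / cell), nx);
    int cy = clampc((int)std::floor((y - lo[1]) / cell), ny);
    int cz = clampc((int)std::floor((z - lo[2]) / cell), nz);
    return (size_t)cx + (size_t)nx * ((size_t)cy + (size_t)ny * cz);
  }

  // nearest neighbour by expanding Chebyshev rings of grid cells
  int nearest(double x, double y, double z, double &best_d2) const {
    int cx = clampc((int)std::floor((x - lo[0]) / cell), nx);
    int cy = clampc((int)std::floor((y - lo[1]) / cell), ny);
    int cz = clampc((int)std::floor((z - lo[2]) / cell), nz);
    int best = -1;
    best_d2 = std::numeric_limits<double>::infinity();
    int rmax = std::max(nx, std::max(ny, nz));
    for (int r = 0; r <= rmax; ++r) {
      if (best >= 0) {
        double ring_min = (double)(r - 1) * cell;
        if (ring_min > 0 && ring_min * ring_min > best_d2) break;
      }
      int x0 = cx - r, x1 = cx + r, y0 = cy - r, y1 = cy + r,
          z0 = cz - r, z1 = cz + r;
      for (int iz = z0; iz <= z1; ++iz) {
        if (iz < 0 || iz >= nz) continue;
        for (int iy = y0; iy <= y1; ++iy) {
          if (iy < 0 || iy >= ny) continue;
          for (int ix = x0; ix <= x1; ++ix) {
            if (ix < 0 || ix >= nx) continue;
            // only the ring surface (skip the interior already visited)
            if (r > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1 &&
                iz != z0 && iz != z1)
              continue;
            const std::vector<int> &bucket =
              cells[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)];
            for (int m : bucket) {
              double dx = pts(0, m) - x, dy = pts(1, m) - y, dz = pts(2, m) - z;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best_d2) { best_d2 = d2; best = m; }
            }
          }
        }
      }
    }
    return best;
  }
};

arma::mat kabsch(const arma::mat &src_c, const arma::mat &tgt_c) {
  arma::mat H = src_c * tgt_c.t();   // 3x3 cross-covariance (unnormalized)
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H))
    stop("SVD failure in rigid update");
  if (s[0] <= 1e-12)
    stop("degenerate correspondence: point sets have no spatial spread (rank error)");
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  return V * D * U.t();
}

} // namespace

// [[Rcpp::export(name = ".icpCpp")]]
List icp_cpp(NumericMatrix source, NumericMatrix target, int max_iter,
             double tol) {
  arma::mat src(source.begin(), source.nrow(), 3, false);
  arma::mat tgt(target.begin(), target.nrow(), 3, false);
  arma::mat S = src.t();             // 3 x N
  arma::mat T = tgt.t();             // 3 x M
  if (S.n_cols < 3 || T.n_cols < 3)
    stop("ICP needs at least 3 points in each cloud");

  // cell size ~ mean nn spacing of a lattice cloud; 2 voxels works well for
  // segmentation clouds and degrades gracefully otherwise
  GridIndex grid(T, 2.0);

  arma::mat R = arma::eye(3, 3);
  arma::vec t = arma::zeros(3);
  double prev_rms = std::numeric_limits<double>::infinity();
  double rms = prev_rms;
  std::vector<double> history;
  arma::vec s_mean = arma::mean(S, 1);
  if (arma::norm(arma::max(S, 1) - arma::min(S, 1)) <= 1e-12)
    stop("degenerate correspondence: source points coincident (rank error)");

  arma::mat matched(3, S.n_cols);
  for (int it = 0; it < max_iter; ++it) {
    arma::mat Sx = R * S;
    Sx.each_col() += t;
    double acc = 0.0;
    for (arma::uword n = 0; n < Sx.n_cols; ++n) {
      double d2;
      int m = grid.nearest(Sx(0, n), Sx(1, n), Sx(2, n), d2);
      matched.col(n) = grid.pts.col(m);
      acc += d2;
    }
    // re-fit the composite transform from the ORIGINAL source
    arma::vec m_mean = arma::mean(matched, 1);
    arma::mat Sc = S.each_col() - s_mean;
    arma::mat Mc = matched.each_col() - m_mean;
    R = kabsch(Sc, Mc);
    t = m_mean - R * s_mean;
    // residual under the updated transform, against current correspondences
    arma::mat Sy = R * S;
    Sy.each_col() += t;
    rms = std::sqrt(arma::accu(arma::square(Sy - matched)) / (double)S.n_cols);
    history.push_back(rms);
    if (it > 0 && std::fabs(prev_rms - rms) <= tol * std::max(prev_rms, 1e-12))
      break;
    prev_rms = rms;
  }

  return List::create(_["rotation"] = wrap(R), _["translation"] = wrap(t),
                      _["rms"] = rms, _["history"] = wrap(history));
}
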