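// Windowed second-moment kernels for 3D fiber orientation (weighted vector
// summation) and 3D directional variance.  Arrays are R arrays in (z, y, x)
// index order, column-major: idx = z + nz*(y + ny*x).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_local_orientation(NumericVector inten, IntegerVector dims,
                           NumericVector voxel, IntegerVector half,
                           LogicalVector compute) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int hz = half[0], hy = half[1], hx = half[2];
  const double vz = voxel[0], vy = voxel[1], vx = voxel[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector ux(n, NA_REAL), uy(n, NA_REAL), uz(n, NA_REAL);
  NumericVector l1(n, NA_REAL), l2(n, NA_REAL), l3(n, NA_REAL);
  LogicalVector valid(n, false);
  arma::mat33 M;
  arma::vec3 eigval;
  arma::mat33 eigvec;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t c = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!compute[c]) continue;
        M.zeros();
        double wsum = 0.0;
        const int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        const int y0 = std::max(0, y - hy), y1 = std::min(ny - 1, y + hy);
        const int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
        for (int px = x0; px <= x1; ++px) {
          const double dx = (px - x) * vx;
          for (int py = y0; py <= y1; ++py) {
            const double dy = (py - y) * vy;
            for (int pz = z0; pz <= z1; ++pz) {
              if (px == x && py == y && pz == z) continue;
              // weight = minimum intensity along the voxel ray c -> p:
              // fibers are continuous bright ridges, so paths that cross a
              // dark gap (toward a neighboring fiber) carry no weight
              const int steps = std::max(std::abs(px - x),
                                 std::max(std::abs(py - y),
                                          std::abs(pz - z)));
              double w = inten[pz + (R_xlen_t)nz * (py + (R_xlen_t)ny * px)];
              for (int s = 1; s < steps && w > 0.0; ++s) {
                const double t = (double)s / steps;
                const int sz = z + (int)std::lround(t * (pz - z));
                const int sy = y + (int)std::lround(t * (py - y));
                const int sx = x + (int)std::lround(t * (px - x));
                const double wi =
                  inten[sz + (R_xlen_t)nz * (sy + (R_xlen_t)ny * sx)];
                if (wi < w) w = wi;
              }
              if (w <= 0.0) continue;
              const double dz = (pz - z) * vz;
              const double norm = std::sqrt(dx * dx + dy * dy + dz * dz);
              const double a = dx / norm, b = dy / norm, cc = dz / norm;
              M(0, 0) += w * a * a; M(0, 1) += w * a * b; M(0, 2) += w * a * cc;
              M(1, 1) += w * b * b; M(1, 2) += w * b * cc;
              M(2, 2) += w * cc * cc;
              wsum += w;
            }
          }
        }
        if (wsum <= 0.0) continue;
        M(1, 0) = M(0, 1); M(2, 0) = M(0, 2); M(2, 1) = M(1, 2);
        arma::eig_sym(eigval, eigvec, M);
        // principal (largest-eigenvalue) axis of the weighted dyadic sum;
        // eigenvalues (descending) let the caller reject voxels whose
        // tensor is planar or degenerate (no single fiber direction)
        ux[c] = eigvec(0, 2); uy[c] = eigvec(1, 2); uz[c] = eigvec(2, 2);
        l1[c] = eigval(2); l2[c] = eigval(1); l3[c] = eigval(0);
        valid[c] = true;
      }
    }
  }
  return List::create(_["ux"] = ux, _["uy"] = uy, _["uz"] = uz,
                      _["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["valid"] = valid);
}

// [[Rcpp::export]]
List cpp_directional_variance(NumericVector ux, NumericVector uy,
                              NumericVector uz, LogicalVector valid,
                              IntegerVector dims, IntegerVector half,
                              int min_count) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int hz = half[0], hy = half[1], hx = half[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector V(n, NA_REAL);
  LogicalVector vout(n, false);
  arma::mat33 T;
  arma::vec3 eigval;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t c = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!valid[c]) continue;
        T.zeros();
        int count = 0;
        const int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        const int y0 = std::max(0, y - hy), y1 = std::min(ny - 1, y + hy);
        const int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
        for (int px = x0; px <= x1; ++px) {
          for (int py = y0; py <= y1; ++py) {
            for (int pz = z0; pz <= z1; ++pz) {
              const R_xlen_t p =
                pz + (R_xlen_t)nz * (py + (R_xlen_t)ny * px);
              if (!valid[p]) continue;
              const double a = ux[p], b = uy[p], cc = uz[p];
              T(0, 0) += a * a; T(0, 1) += a * b; T(0, 2) += a * cc;
              T(1, 1) += b * b; T(1, 2) += b * cc;
              T(2, 2) += cc * cc;
              ++count;
            }
          }
        }
        if (count < min_count) continue;
        T /= count;
        T(1, 0) = T(0, 1); T(2, 0) = T(0, 2); T(2, 1) = T(1, 2);
        arma::eig_sym(eigval, T);
        double v = 1.5 * (1.0 - eigval(2));
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
        V[c] = v;
        vout[c] = true;
      }
    }
  }
  return List::create(_["V"] = V, _["valid"] = vout);
}
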