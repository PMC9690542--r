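// Support operations: connected-component labelling on the voxel grid,
// in-plane affine resampling and Gaussian blurring (used by the sagittal
// augmentation pipeline).

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <cstring>

// Connected components of voxels with labels == cls.
// connectivity: 6 or 26.  Returns component ids (1..K), 0 elsewhere.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(Rcpp::IntegerVector labels,
                                         Rcpp::IntegerVector dims, int cls,
                                         int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  Rcpp::IntegerVector comp(N);
  std::memset(INTEGER(comp), 0, N * sizeof(int));
  const int* lab = INTEGER(labels);
  int* cmp = INTEGER(comp);

  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
          continue;
        nbr.push_back({dx, dy, dz});
      }

  std::vector<size_t> stack;
  int next_id = 0;
  for (size_t s = 0; s < N; ++s) {
    if (lab[s] != cls || cmp[s] != 0) continue;
    ++next_id;
    cmp[s] = next_id;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int ix = v % nx, iy = (v / nx) % ny, iz = v / ((size_t)nx * ny);
      for (const auto& d : nbr) {
        int x2 = ix + d[0], y2 = iy + d[1], z2 = iz + d[2];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        size_t v2 = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
        if (lab[v2] == cls && cmp[v2] == 0) {
          cmp[v2] = next_id;
          stack.push_back(v2);
        }
      }
    }
  }
  comp.attr("n_components") = next_id;
  return comp;
}

// Apply the same 2D affine map to every slice of a volume (x, y are
// in-plane, z the slice axis).  The map is the *inverse* transform:
// source = A %*% (dest - centre) + centre + shift.  Out-of-range source
// coordinates are clamped to the edge (replicate padding).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_resample_inplane(Rcpp::NumericVector vol,
                                         Rcpp::IntegerVector dims,
                                         Rcpp::NumericMatrix A,
                                         Rcpp::NumericVector shift,
                                         bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  Rcpp::NumericVector out((size_t)nx * ny * nz);
  const double* src = REAL(vol);
  double* dst = REAL(out);
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const double sx = shift[0], sy = shift[1];
  for (int iz = 0; iz < nz; ++iz) {
    const double* sp = src + (size_t)nx * ny * iz;
    double* dp = dst + (size_t)nx * ny * iz;
    for (int iy = 0; iy < ny; ++iy) {
      const double ry = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        const double rx = ix - cx;
        double u = a11 * rx + a12 * ry + cx + sx;
        double v = a21 * rx + a22 * ry + cy + sy;
        if (nearest) {
          int ui = (int)std::lround(u), vi = (int)std::lround(v);
          ui = std::min(std::max(ui, 0), nx - 1);
          vi = std::min(std::max(vi, 0), ny - 1);
          dp[ix + (size_t)nx * iy] = sp[ui + (size_t)nx * vi];
        } else {
          u = std::min(std::max(u, 0.0), nx - 1.0);
          v = std::min(std::max(v, 0.0), ny - 1.0);
          int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
          int u1 = std::min(u0 + 1, nx - 1), v1 = std::min(v0 + 1, ny - 1);
          double fu = u - u0, fv = v - v0;
          double val = (1 - fu) * (1 - fv) * sp[u0 + (size_t)nx * v0] +
                       fu * (1 - fv) * sp[u1 + (size_t)nx * v0] +
                       (1 - fu) * fv * sp[u0 + (size_t)nx * v1] +
                       fu * fv * sp[u1 + (size_t)nx * v1];
          dp[ix + (size_t)nx * iy] = val;
        }
      }
    }
  }
  return out;
}

// Separable in-plane Gaussian blur (sigma in voxels); slices independent.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_blur_inplane(Rcpp::NumericVector vol,
                                     Rcpp::IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Rcpp::NumericVector out = Rcpp::clone(vol);
  if (sigma <= 0) return out;
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;

  std::vector<double> tmp((size_t)nx * ny);
  double* dst = REAL(out);
  for (int iz = 0; iz < nz; ++iz) {
    double* pl = dst + (size_t)nx * ny * iz;
    // along x
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double acc = 0;
        for (int i = -rad; i <= rad; ++i) {
          int x2 = std::min(std::max(ix + i, 0), nx - 1);
          acc += k[i + rad] * pl[x2 + (size_t)nx * iy];
        }
        tmp[ix + (size_t)nx * iy] = acc;
      }
    // along y
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double acc = 0;
        for (int i = -rad; i <= rad; ++i) {
          int y2 = std::min(std::max(iy + i, 0), ny - 1);
          acc += k[i + rad] * tmp[ix + (size_t)nx * y2];
        }
        pl[ix + (size_t)nx * iy] = acc;
      }
  }
  return out;
}
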