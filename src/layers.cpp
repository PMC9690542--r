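// Low-level layers for the anisotropic residual 3D U-Net.
//
// Activation layout: fmat of size (N x C) where N = nx*ny*nz voxels in
// column-major spatial order v = ix + nx*(iy + ny*iz), and C channels.
// Axes: x, y are the in-plane (sagittal) axes, z is the slice axis.
// Convolution kernels are given as extents (kz, ky, kx); below depth I
// kz == 1 so the network never mixes information across slices there.
//
// Convolutions are evaluated as im2col + GEMM on single-precision
// matrices (colT is N x K with K = Cin*kz*ky*kx), so nearly all work is
// a BLAS sgemm call.  Weights are stored as (K x Cout) matrices whose
// row order matches the colT column order:
//   r = ((ci*kz + dz)*ky + dy)*kx + dx.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "layers.h"

using namespace arma;

void im2colT(const fmat& A, int nx, int ny, int nz,
             int kz, int ky, int kx, fmat& colT) {
  const int N = nx * ny * nz;
  const int Cin = A.n_cols;
  const int cz = kz / 2, cy = ky / 2, cx = kx / 2;
  colT.set_size(N, Cin * kz * ky * kx);
  for (int ci = 0; ci < Cin; ++ci) {
    const float* src = A.colptr(ci);
    for (int dz = 0; dz < kz; ++dz) {
      const int offz = dz - cz;
      for (int dy = 0; dy < ky; ++dy) {
        const int offy = dy - cy;
        for (int dx = 0; dx < kx; ++dx) {
          const int offx = dx - cx;
          const int r = ((ci * kz + dz) * ky + dy) * kx + dx;
          float* dst = colT.colptr(r);
          for (int iz = 0; iz < nz; ++iz) {
            const int z2 = iz + offz;
            for (int iy = 0; iy < ny; ++iy) {
              const int y2 = iy + offy;
              float* drow = dst + (size_t)nx * (iy + (size_t)ny * iz);
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny) {
                std::memset(drow, 0, sizeof(float) * nx);
                continue;
              }
              const float* srow = src + (size_t)nx * (y2 + (size_t)ny * z2);
              // dst[ix] = src[ix + offx] for valid ix
              int lo = std::max(0, -offx);
              int hi = std::min(nx, nx - offx);
              if (lo > 0) std::memset(drow, 0, sizeof(float) * lo);
              if (hi > lo)
                std::memcpy(drow + lo, srow + lo + offx,
                            sizeof(float) * (hi - lo));
              if (hi < nx) std::memset(drow + hi, 0, sizeof(float) * (nx - hi));
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2colT: dA(v + off, ci) += dColT(v, r).
void col2imT(const fmat& dColT, int nx, int ny, int nz,
             int kz, int ky, int kx, fmat& dA) {
  const int Cin = dA.n_cols;
  const int cz = kz / 2, cy = ky / 2, cx = kx / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    float* dst = dA.colptr(ci);
    for (int dz = 0; dz < kz; ++dz) {
      const int offz = dz - cz;
      for (int dy = 0; dy < ky; ++dy) {
        const int offy = dy - cy;
        for (int dx = 0; dx < kx; ++dx) {
          const int offx = dx - cx;
          const int r = ((ci * kz + dz) * ky + dy) * kx + dx;
          const float* src = dColT.colptr(r);
          for (int iz = 0; iz < nz; ++iz) {
            const int z2 = iz + offz;
            if (z2 < 0 || z2 >= nz) continue;
            for (int iy = 0; iy < ny; ++iy) {
              const int y2 = iy + offy;
              if (y2 < 0 || y2 >= ny) continue;
              const float* srow = src + (size_t)nx * (iy + (size_t)ny * iz);
              float* drow = dst + (size_t)nx * (y2 + (size_t)ny * z2);
              int lo = std::max(0, -offx);
              int hi = std::min(nx, nx - offx);
              for (int ix = lo; ix < hi; ++ix) drow[ix + offx] += srow[ix];
            }
          }
        }
      }
    }
  }
}

void conv_fw(const fmat& A, const fmat& W, const frowvec& b,
             int nx, int ny, int nz, int kz, int ky, int kx,
             fmat& out, fmat& ws) {
  im2colT(A, nx, ny, nz, kz, ky, kx, ws);
  out = ws * W;
  out.each_row() += b;
}

void conv_bw(const fmat& A, const fmat& W, const fmat& dY,
             int nx, int ny, int nz, int kz, int ky, int kx,
             fmat& dA, bool accum_dA, fmat& dW, frowvec& db, fmat& ws) {
  im2colT(A, nx, ny, nz, kz, ky, kx, ws);
  dW = ws.t() * dY;
  db = sum(dY, 0);
  ws = dY * W.t();  // reuse workspace as dColT
  if (!accum_dA) {
    dA.zeros(A.n_rows, A.n_cols);
  }
  col2imT(ws, nx, ny, nz, kz, ky, kx, dA);
}

void relu_inplace(fmat& A) { A.transform([](float v) { return v > 0 ? v : 0.0f; }); }

// Gradient through ReLU given the *output* of the ReLU.
void relu_bw_inplace(fmat& dY, const fmat& Yout) {
  const size_t n = dY.n_elem;
  const float* y = Yout.memptr();
  float* d = dY.memptr();
  for (size_t i = 0; i < n; ++i)
    if (y[i] <= 0) d[i] = 0.0f;
}

// In-plane 2x2 max pooling (slice axis untouched).  nx, ny must be even.
void pool_fw(const fmat& A, int nx, int ny, int nz, fmat& out, umat& idx) {
  const int ox = nx / 2, oy = ny / 2;
  const int Nout = ox * oy * nz;
  const int C = A.n_cols;
  out.set_size(Nout, C);
  idx.set_size(Nout, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    uword* id = idx.colptr(c);
    for (int iz = 0; iz < nz; ++iz)
      for (int jy = 0; jy < oy; ++jy)
        for (int jx = 0; jx < ox; ++jx) {
          const size_t base =
              (size_t)2 * jx + (size_t)nx * (2 * jy + (size_t)ny * iz);
          size_t best = base;
          float bv = src[base];
          const size_t cand[3] = {base + 1, base + nx, base + nx + 1};
          for (int k = 0; k < 3; ++k)
            if (src[cand[k]] > bv) { bv = src[cand[k]]; best = cand[k]; }
          const size_t o = (size_t)jx + (size_t)ox * (jy + (size_t)oy * iz);
          dst[o] = bv;
          id[o] = best;
        }
  }
}

void pool_bw(const fmat& dOut, const umat& idx, int Nin, fmat& dIn) {
  const int C = dOut.n_cols;
  dIn.zeros(Nin, C);
  for (int c = 0; c < C; ++c) {
    const float* d = dOut.colptr(c);
    const uword* id = idx.colptr(c);
    float* o = dIn.colptr(c);
    for (size_t i = 0; i < dOut.n_rows; ++i) o[id[i]] += d[i];
  }
}

// Nearest-neighbour in-plane x2 upsampling from coarse (nx, ny, nz).
void up_fw(const fmat& A, int nx, int ny, int nz, fmat& out) {
  const int fx = 2 * nx, fy = 2 * ny;
  const int Nout = fx * fy * nz;
  const int C = A.n_cols;
  out.set_size(Nout, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < fy; ++iy) {
        const float* srow = src + (size_t)nx * (iy / 2 + (size_t)ny * iz);
        float* drow = dst + (size_t)fx * (iy + (size_t)fy * iz);
        for (int ix = 0; ix < fx; ++ix) drow[ix] = srow[ix / 2];
      }
  }
}

void up_bw(const fmat& dFine, int nx, int ny, int nz, fmat& dCoarse) {
  // nx, ny, nz are the *coarse* dims
  const int fx = 2 * nx, fy = 2 * ny;
  const int C = dFine.n_cols;
  dCoarse.zeros((size_t)nx * ny * nz, C);
  for (int c = 0; c < C; ++c) {
    const float* src = dFine.colptr(c);
    float* dst = dCoarse.colptr(c);
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < fy; ++iy) {
        const float* srow = src + (size_t)fx * (iy + (size_t)fy * iz);
        float* drow = dst + (size_t)nx * (iy / 2 + (size_t)ny * iz);
        for (int ix = 0; ix < fx; ++ix) drow[ix / 2] += srow[ix];
      }
  }
}

// Row-wise softmax followed by focal cross-entropy against integer labels
// (0-based).  Returns the mean loss; writes the gradient w.r.t. the
// logits (already divided by N) into dZ when want_grad.
double softmax_focal(const fmat& logits, const Rcpp::IntegerVector& labels,
                     double gamma, fmat* dZ, fmat* probs_out) {
  const int N = logits.n_rows, C = logits.n_cols;
  const double eps = 1e-12;
  double loss = 0.0;
  if (dZ) dZ->set_size(N, C);
  if (probs_out) probs_out->set_size(N, C);
  std::vector<double> p(C);
  for (int i = 0; i < N; ++i) {
    double m = -1e30;
    for (int c = 0; c < C; ++c) m = std::max(m, (double)logits(i, c));
    double s = 0.0;
    for (int c = 0; c < C; ++c) { p[c] = std::exp((double)logits(i, c) - m); s += p[c]; }
    for (int c = 0; c < C; ++c) p[c] /= s;
    if (probs_out)
      for (int c = 0; c < C; ++c) (*probs_out)(i, c) = (float)p[c];
    const int t = labels[i];
    double pt = std::max(p[t], eps);
    double one_m = 1.0 - pt;
    loss += std::pow(one_m, gamma) * (-std::log(pt));
    if (dZ) {
      double t1 = (gamma > 0.0 && one_m > eps)
                      ? gamma * std::pow(one_m, gamma - 1.0) * std::log(pt)
                      : 0.0;
      double t2 = -std::pow(one_m, gamma) / pt;
      double a = (t1 + t2) * pt / N;  // dL/dz_k = a*(delta_tk - p_k)
      for (int c = 0; c < C; ++c) (*dZ)(i, c) = (float)(-a * p[c]);
      (*dZ)(i, t) += (float)a;
    }
  }
  return loss / N;
}

// ---- R-facing primitives (used by unit tests and the reference forward) --

static fmat as_fmat(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

// x: (N x Cin) matrix, dims c(nx,ny,nz), W: (K x Cout), b: Cout
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv3d(Rcpp::NumericMatrix x, Rcpp::IntegerVector dims,
                               Rcpp::NumericMatrix W, Rcpp::NumericVector b,
                               Rcpp::IntegerVector kernel) {
  fmat A = as_fmat(x), Wf = as_fmat(W);
  frowvec bf(W.ncol());
  for (int i = 0; i < b.size(); ++i) bf(i) = (float)b[i];
  fmat out, ws;
  conv_fw(A, Wf, bf, dims[0], dims[1], dims[2], kernel[0], kernel[1], kernel[2],
          out, ws);
  return Rcpp::wrap(conv_to<mat>::from(out));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_maxpool_inplane(Rcpp::NumericMatrix x,
                                        Rcpp::IntegerVector dims) {
  fmat A = as_fmat(x), out;
  umat idx;
  pool_fw(A, dims[0], dims[1], dims[2], out, idx);
  return Rcpp::wrap(conv_to<mat>::from(out));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_upsample_inplane(Rcpp::NumericMatrix x,
                                         Rcpp::IntegerVector dims) {
  fmat A = as_fmat(x), out;
  up_fw(A, dims[0], dims[1], dims[2], out);
  return Rcpp::wrap(conv_to<mat>::from(out));
}
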