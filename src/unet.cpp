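// Composed forward / backward pass of the depth-D residual 3D U-Net.
//
// Topology (D = depth, feats = features per depth, encB/decB = residual
// blocks per encoder/decoder stage):
//   encoder d: [pool 1x2x2 if d>1] -> lift conv+ReLU -> encB residual blocks
//   decoder d (d = D-1..1): NN-upsample(dec[d+1]) concat enc[d]
//                           -> lift conv+ReLU -> decB residual blocks
//   head: 1x1x1 convolution to n_classes, softmax over channels
// Kernels are (3,3,3) at depth I and (1,3,3) below, so only depth I mixes
// information across slices.  Residual block: out = in + F(in) with
// F = ReLU(conv2(ReLU(conv1(in)))).
//
// The weight list order here must match build_network() on the R side:
//   enc d=1..D: lift W,b; then per block conv1 W,b, conv2 W,b
//   dec d=D-1..1: lift W,b; then per block conv1 W,b, conv2 W,b
//   final W,b

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "layers.h"

using namespace arma;

namespace {

struct Params {
  std::vector<fmat> W;
  std::vector<frowvec> b;
};

Params parse_weights(const Rcpp::List& weights) {
  Params P;
  for (int i = 0; i < weights.size(); i += 2) {
    Rcpp::NumericMatrix Wm = weights[i];
    Rcpp::NumericVector bv = weights[i + 1];
    fmat Wf(Wm.nrow(), Wm.ncol());
    for (int j = 0; j < Wm.ncol(); ++j)
      for (int r = 0; r < Wm.nrow(); ++r) Wf(r, j) = (float)Wm(r, j);
    frowvec bf(bv.size());
    for (int j = 0; j < bv.size(); ++j) bf(j) = (float)bv[j];
    P.W.push_back(std::move(Wf));
    P.b.push_back(std::move(bf));
  }
  return P;
}

struct Dims { int nx, ny, nz; int N() const { return nx * ny * nz; } };

void kern(int d, int& kz, int& ky, int& kx) {
  kz = (d == 1) ? 3 : 1; ky = 3; kx = 3;
}

struct Cache {
  std::vector<Dims> dim;                       // per depth (1-based)
  std::vector<fmat> enc_in, enc_lift;          // per depth
  std::vector<std::vector<fmat>> eb_in, eb_t1, eb_t2;
  std::vector<fmat> enc_out;
  std::vector<umat> pool_idx;                  // pool into depth d (d>=2)
  std::vector<fmat> dec_cat, dec_lift;
  std::vector<std::vector<fmat>> db_in, db_t1, db_t2;
  std::vector<fmat> dec_out;
  fmat logits;
};

// Forward pass; fills cache when keep is true.
void unet_fw(const Params& P, const std::vector<int>& feats, int encB,
             int decB, int ncls, const fmat& x, int nx, int ny, int nz,
             Cache& C, fmat& ws) {
  const int D = (int)feats.size();
  C.dim.assign(D + 1, {0, 0, 0});
  C.enc_in.resize(D + 1); C.enc_lift.resize(D + 1); C.enc_out.resize(D + 1);
  C.eb_in.assign(D + 1, {}); C.eb_t1.assign(D + 1, {}); C.eb_t2.assign(D + 1, {});
  C.pool_idx.resize(D + 1);
  C.dec_cat.resize(D + 1); C.dec_lift.resize(D + 1); C.dec_out.resize(D + 1);
  C.db_in.assign(D + 1, {}); C.db_t1.assign(D + 1, {}); C.db_t2.assign(D + 1, {});

  int w = 0;  // weight cursor
  for (int d = 1; d <= D; ++d) {
    Dims dm{nx >> (d - 1), ny >> (d - 1), nz};
    C.dim[d] = dm;
    if (d == 1) {
      C.enc_in[d] = x;
    } else {
      pool_fw(C.enc_out[d - 1], C.dim[d - 1].nx, C.dim[d - 1].ny, nz,
              C.enc_in[d], C.pool_idx[d]);
    }
    int kz, ky, kx; kern(d, kz, ky, kx);
    conv_fw(C.enc_in[d], P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx,
            C.enc_lift[d], ws);
    ++w;
    relu_inplace(C.enc_lift[d]);
    fmat cur = C.enc_lift[d];
    for (int bI = 0; bI < encB; ++bI) {
      C.eb_in[d].push_back(cur);
      fmat t1, t2;
      conv_fw(cur, P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx, t1, ws); ++w;
      relu_inplace(t1);
      conv_fw(t1, P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx, t2, ws); ++w;
      relu_inplace(t2);
      cur += t2;
      C.eb_t1[d].push_back(std::move(t1));
      C.eb_t2[d].push_back(std::move(t2));
    }
    C.enc_out[d] = std::move(cur);
  }

  fmat dec_prev = C.enc_out[D];
  for (int d = D - 1; d >= 1; --d) {
    const Dims& dm = C.dim[d];
    fmat up;
    up_fw(dec_prev, C.dim[d + 1].nx, C.dim[d + 1].ny, nz, up);
    C.dec_cat[d] = join_rows(C.enc_out[d], up);
    int kz, ky, kx; kern(d, kz, ky, kx);
    conv_fw(C.dec_cat[d], P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx,
            C.dec_lift[d], ws);
    ++w;
    relu_inplace(C.dec_lift[d]);
    fmat cur = C.dec_lift[d];
    for (int bI = 0; bI < decB; ++bI) {
      C.db_in[d].push_back(cur);
      fmat t1, t2;
      conv_fw(cur, P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx, t1, ws); ++w;
      relu_inplace(t1);
      conv_fw(t1, P.W[w], P.b[w], dm.nx, dm.ny, dm.nz, kz, ky, kx, t2, ws); ++w;
      relu_inplace(t2);
      cur += t2;
      C.db_t1[d].push_back(std::move(t1));
      C.db_t2[d].push_back(std::move(t2));
    }
    C.dec_out[d] = cur;
    dec_prev = std::move(cur);
  }

  // 1x1x1 classification head
  C.logits = C.dec_out[1] * P.W[w];
  C.logits.each_row() += P.b[w];
}

// Backward through one residual block; dOut is consumed, returns d(input).
fmat resblock_bw(const fmat& blk_in, const fmat& t1, const fmat& t2,
                 const fmat& W1, const fmat& W2, const Dims& dm,
                 int kz, int ky, int kx, fmat& dOut,
                 fmat& dW1, frowvec& db1, fmat& dW2, frowvec& db2, fmat& ws) {
  fmat dA = dOut;  // identity path
  relu_bw_inplace(dOut, t2);
  fmat dT1;
  conv_bw(t1, W2, dOut, dm.nx, dm.ny, dm.nz, kz, ky, kx, dT1, false, dW2, db2,
          ws);
  relu_bw_inplace(dT1, t1);
  conv_bw(blk_in, W1, dT1, dm.nx, dm.ny, dm.nz, kz, ky, kx, dA, true, dW1, db1,
          ws);
  return dA;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_unet_forward(Rcpp::List weights,
                                     Rcpp::IntegerVector feats, int enc_blocks,
                                     int dec_blocks, int n_classes,
                                     Rcpp::NumericVector x,
                                     Rcpp::IntegerVector dims,
                                     bool softmax = true) {
  Params P = parse_weights(weights);
  std::vector<int> f(feats.begin(), feats.end());
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  fmat xin((size_t)nx * ny * nz, 1);
  for (size_t i = 0; i < xin.n_rows; ++i) xin(i, 0) = (float)x[i];
  Cache C; fmat ws;
  unet_fw(P, f, enc_blocks, dec_blocks, n_classes, xin, nx, ny, nz, C, ws);
  if (!softmax) return Rcpp::wrap(conv_to<mat>::from(C.logits));
  fmat probs;
  Rcpp::IntegerVector dummy(C.logits.n_rows);  // labels unused for probs
  softmax_focal(C.logits, dummy, 0.0, nullptr, &probs);
  return Rcpp::wrap(conv_to<mat>::from(probs));
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_loss_grad(Rcpp::List weights, Rcpp::IntegerVector feats,
                              int enc_blocks, int dec_blocks, int n_classes,
                              Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                              Rcpp::IntegerVector labels0, double gamma) {
  Params P = parse_weights(weights);
  std::vector<int> f(feats.begin(), feats.end());
  const int D = (int)f.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  fmat xin((size_t)nx * ny * nz, 1);
  for (size_t i = 0; i < xin.n_rows; ++i) xin(i, 0) = (float)x[i];

  Cache C; fmat ws;
  unet_fw(P, f, enc_blocks, dec_blocks, n_classes, xin, nx, ny, nz, C, ws);

  fmat dZ;
  double loss = softmax_focal(C.logits, labels0, gamma, &dZ, nullptr);

  const int nW = (int)P.W.size();
  std::vector<fmat> gW(nW);
  std::vector<frowvec> gb(nW);

  // weight cursor positions mirror the forward traversal
  int head = nW - 1;
  // head backward
  gW[head] = C.dec_out[1].t() * dZ;
  gb[head] = sum(dZ, 0);
  fmat dDec = dZ * P.W[head].t();  // grad at dec_out[1]

  // decoder stages were created for d = D-1..1 with cursor after encoders
  int enc_w_count = 0;
  for (int d = 1; d <= D; ++d) enc_w_count += 1 + 2 * enc_blocks;
  std::vector<int> dec_w0(D + 1, -1);
  {
    int w = enc_w_count;
    for (int d = D - 1; d >= 1; --d) { dec_w0[d] = w; w += 1 + 2 * dec_blocks; }
  }
  std::vector<int> enc_w0(D + 1, -1);
  {
    int w = 0;
    for (int d = 1; d <= D; ++d) { enc_w0[d] = w; w += 1 + 2 * enc_blocks; }
  }

  std::vector<fmat> dEnc(D + 1);  // accumulated grads at enc_out[d]

  // walk decoder from fine (d=1) to coarse
  for (int d = 1; d <= D - 1; ++d) {
    const Dims& dm = C.dim[d];
    int kz, ky, kx; kern(d, kz, ky, kx);
    int w = dec_w0[d];
    // residual blocks backward (reverse order)
    for (int bI = dec_blocks - 1; bI >= 0; --bI) {
      int wc1 = w + 1 + 2 * bI, wc2 = wc1 + 1;
      dDec = resblock_bw(C.db_in[d][bI], C.db_t1[d][bI], C.db_t2[d][bI],
                         P.W[wc1], P.W[wc2], dm, kz, ky, kx, dDec,
                         gW[wc1], gb[wc1], gW[wc2], gb[wc2], ws);
    }
    relu_bw_inplace(dDec, C.dec_lift[d]);
    fmat dCat;
    conv_bw(C.dec_cat[d], P.W[w], dDec, dm.nx, dm.ny, dm.nz, kz, ky, kx, dCat,
            false, gW[w], gb[w], ws);
    // split: first feats[d-1] cols -> skip, rest -> upsampled deeper decoder
    fmat dSkip = dCat.cols(0, f[d - 1] - 1);
    fmat dUpFine = dCat.cols(f[d - 1], dCat.n_cols - 1);
    if (dEnc[d].n_elem == 0) dEnc[d] = dSkip; else dEnc[d] += dSkip;
    up_bw(dUpFine, C.dim[d + 1].nx, C.dim[d + 1].ny, nz, dDec);
    // dDec is now the grad at dec_out[d+1] (or enc_out[D] when d+1 == D)
  }
  if (D >= 2) {
    if (dEnc[D].n_elem == 0) dEnc[D] = dDec; else dEnc[D] += dDec;
  } else {
    dEnc[1] = dDec;
  }

  // encoder backward from deep to shallow
  for (int d = D; d >= 1; --d) {
    const Dims& dm = C.dim[d];
    int kz, ky, kx; kern(d, kz, ky, kx);
    int w = enc_w0[d];
    fmat dCur = std::move(dEnc[d]);
    for (int bI = enc_blocks - 1; bI >= 0; --bI) {
      int wc1 = w + 1 + 2 * bI, wc2 = wc1 + 1;
      dCur = resblock_bw(C.eb_in[d][bI], C.eb_t1[d][bI], C.eb_t2[d][bI],
                         P.W[wc1], P.W[wc2], dm, kz, ky, kx, dCur,
                         gW[wc1], gb[wc1], gW[wc2], gb[wc2], ws);
    }
    relu_bw_inplace(dCur, C.enc_lift[d]);
    fmat dIn;
    conv_bw(C.enc_in[d], P.W[w], dCur, dm.nx, dm.ny, dm.nz, kz, ky, kx, dIn,
            false, gW[w], gb[w], ws);
    if (d > 1) {
      fmat dPrev;
      pool_bw(dIn, C.pool_idx[d], C.dim[d - 1].N(), dPrev);
      if (dEnc[d - 1].n_elem == 0) dEnc[d - 1] = std::move(dPrev);
      else dEnc[d - 1] += dPrev;
    }
  }

  Rcpp::List grads(2 * nW);
  for (int i = 0; i < nW; ++i) {
    grads[2 * i] = Rcpp::wrap(conv_to<mat>::from(gW[i]));
    grads[2 * i + 1] = Rcpp::NumericVector(gb[i].begin(), gb[i].end());
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export]]
Rcpp::List cpp_softmax_focal(Rcpp::NumericMatrix logits,
                             Rcpp::IntegerVector labels0, double gamma) {
  fmat L(logits.nrow(), logits.ncol());
  for (int j = 0; j < logits.ncol(); ++j)
    for (int i = 0; i < logits.nrow(); ++i) L(i, j) = (float)logits(i, j);
  fmat dZ, probs;
  double loss = softmax_focal(L, labels0, gamma, &dZ, &probs);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grad") = Rcpp::wrap(conv_to<mat>::from(dZ)),
      Rcpp::Named("probs") = Rcpp::wrap(conv_to<mat>::from(probs)));
}
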