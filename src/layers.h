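#ifndef SPINEMORPH_LAYERS_H
#define SPINEMORPH_LAYERS_H

#include <RcppArmadillo.h>

void im2colT(const arma::fmat& A, int nx, int ny, int nz,
             int kz, int ky, int kx, arma::fmat& colT);
void col2imT(const arma::fmat& dColT, int nx, int ny, int nz,
             int kz, int ky, int kx, arma::fmat& dA);
void conv_fw(const arma::fmat& A, const arma::fmat& W, const arma::frowvec& b,
             int nx, int ny, int nz, int kz, int ky, int kx,
             arma::fmat& out, arma::fmat& ws);
void conv_bw(const arma::fmat& A, const arma::fmat& W, const arma::fmat& dY,
             int nx, int ny, int nz, int kz, int ky, int kx,
             arma::fmat& dA, bool accum_dA, arma::fmat& dW, arma::frowvec& db,
             arma::fmat& ws);
void relu_inplace(arma::fmat& A);
void relu_bw_inplace(arma::fmat& dY, const arma::fmat& Yout);
void pool_fw(const arma::fmat& A, int nx, int ny, int nz,
             arma::fmat& out, arma::umat& idx);
void pool_bw(const arma::fmat& dOut, const arma::umat& idx, int Nin,
             arma::fmat& dIn);
void up_fw(const arma::fmat& A, int nx, int ny, int nz, arma::fmat& out);
void up_bw(const arma::fmat& dFine, int nx, int ny, int nz,
           arma::fmat& dCoarse);
double softmax_focal(const arma::fmat& logits,
                     const Rcpp::IntegerVector& labels, double gamma,
                     arma::fmat* dZ, arma::fmat* probs_out);

#endif
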