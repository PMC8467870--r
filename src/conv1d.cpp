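// Valid (no-padding) 1D convolution and length-2 max-pooling kernels for
// the waveform CNN.  Data arrive as double arrays from R; the GEMM work
// runs in single precision (ample for gradient training, ~2x the
// throughput on these long segments).  Batches are processed in chunks
// so the im2col buffer stays within a fixed memory budget.
//
// Layout conventions (match the R-side nn engine):
//   x    : cube  (L_in,  C_in,  B)   one slice per sample
//   W    : matrix(K * C_in, C_out)   row index r = cin * K + k
//   b    : vector(C_out)
//   out  : cube  (L_out, C_out, B),  L_out = L_in - K + 1

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const arma::uword COL_BUDGET = 64000000;  // floats in im2col buffer

static int chunk_size(int L_out, int KC, int B) {
  arma::uword per = (arma::uword)L_out * KC;
  int m = (int)std::max((arma::uword)1, COL_BUDGET / std::max(per, (arma::uword)1));
  return std::min(m, B);
}

static void im2col_chunk(const arma::fcube& xf, int s0, int m, int K,
                         arma::fmat& col) {
  const int L_out = xf.n_rows - K + 1;
  const int C_in = xf.n_cols;
  for (int s = 0; s < m; ++s) {
    const arma::fmat& xs = xf.slice(s0 + s);
    for (int c = 0; c < C_in; ++c) {
      const float* src = xs.colptr(c);
      for (int k = 0; k < K; ++k)
        std::memcpy(col.colptr(c * K + k) + (arma::uword)s * L_out,
                    src + k, sizeof(float) * L_out);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv1d_forward(NumericVector x, NumericMatrix W,
                                 NumericVector b, int K, bool relu) {
  IntegerVector dims = x.attr("dim");
  const int L_in = dims[0], C_in = dims[1], B = dims[2];
  const int C_out = W.ncol();
  const int L_out = L_in - K + 1;
  if (L_out < 1) stop("input length %d shorter than kernel %d", L_in, K);
  if (W.nrow() != K * C_in) stop("weight rows != K * C_in");

  arma::cube xd(x.begin(), L_in, C_in, B, false);
  arma::fcube xf = arma::conv_to<arma::fcube>::from(xd);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(b.begin(), b.size(), false));

  NumericVector out(static_cast<R_xlen_t>(L_out) * C_out * B);
  out.attr("dim") = IntegerVector::create(L_out, C_out, B);
  arma::cube od(out.begin(), L_out, C_out, B, false);

  const int mchunk = chunk_size(L_out, K * C_in, B);
  arma::fmat col((arma::uword)mchunk * L_out, K * C_in);
  for (int s0 = 0; s0 < B; s0 += mchunk) {
    int m = std::min(mchunk, B - s0);
    if (m != mchunk) col.set_size((arma::uword)m * L_out, K * C_in);
    im2col_chunk(xf, s0, m, K, col);
    arma::fmat y = col * Wf;
    y.each_row() += bf;
    if (relu) y.transform([](float v) { return v > 0 ? v : 0.0f; });
    for (int s = 0; s < m; ++s)
      od.slice(s0 + s) = arma::conv_to<arma::mat>::from(
          arma::fmat(y.rows((arma::uword)s * L_out,
                            (arma::uword)(s + 1) * L_out - 1)));
  }
  return out;
}

// backward pass; `out` is the forward output (used only to re-derive the
// ReLU mask when relu = true)
// [[Rcpp::export]]
List cpp_conv1d_backward(NumericVector x, NumericMatrix W,
                         NumericVector out, NumericVector gout, int K,
                         bool relu) {
  IntegerVector dims = x.attr("dim");
  const int L_in = dims[0], C_in = dims[1], B = dims[2];
  const int C_out = W.ncol();
  const int L_out = L_in - K + 1;

  arma::cube xd(x.begin(), L_in, C_in, B, false);
  arma::cube odc(out.begin(), L_out, C_out, B, false);
  arma::cube gdc(gout.begin(), L_out, C_out, B, false);
  arma::fcube xf = arma::conv_to<arma::fcube>::from(xd);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W.begin(), W.nrow(), W.ncol(), false));

  arma::fmat gW(K * C_in, C_out, arma::fill::zeros);
  arma::fvec gb(C_out, arma::fill::zeros);
  NumericVector gx(static_cast<R_xlen_t>(L_in) * C_in * B);
  gx.attr("dim") = IntegerVector::create(L_in, C_in, B);
  arma::cube gxd(gx.begin(), L_in, C_in, B, false);

  const int mchunk = chunk_size(L_out, K * C_in, B);
  arma::fmat col((arma::uword)mchunk * L_out, K * C_in);
  for (int s0 = 0; s0 < B; s0 += mchunk) {
    int m = std::min(mchunk, B - s0);
    if (m != mchunk) col.set_size((arma::uword)m * L_out, K * C_in);
    im2col_chunk(xf, s0, m, K, col);
    // masked upstream gradient for the chunk
    arma::fmat gs((arma::uword)m * L_out, C_out);
    for (int s = 0; s < m; ++s) {
      const double* gp = gdc.slice_memptr(s0 + s);
      const double* op = odc.slice_memptr(s0 + s);
      float* dst = gs.memptr();
      arma::uword off = (arma::uword)s * L_out;
      for (int c = 0; c < C_out; ++c)
        for (int t = 0; t < L_out; ++t) {
          double g = gp[(arma::uword)c * L_out + t];
          if (relu && op[(arma::uword)c * L_out + t] <= 0) g = 0;
          dst[(arma::uword)c * (m * (arma::uword)L_out) + off + t] = (float)g;
        }
    }
    gW += col.t() * gs;
    gb += arma::sum(gs, 0).t();
    arma::fmat gcol = gs * Wf.t();       // (m*L_out, K*C_in)
    for (int s = 0; s < m; ++s) {
      arma::fmat gxs(L_in, C_in, arma::fill::zeros);
      for (int c = 0; c < C_in; ++c) {
        float* dst = gxs.colptr(c);
        for (int k = 0; k < K; ++k) {
          const float* src = gcol.colptr(c * K + k) + (arma::uword)s * L_out;
          float* d2 = dst + k;
          for (int t = 0; t < L_out; ++t) d2[t] += src[t];
        }
      }
      gxd.slice(s0 + s) = arma::conv_to<arma::mat>::from(gxs);
    }
  }

  return List::create(
      _["gx"] = gx,
      _["gW"] = wrap(arma::conv_to<arma::mat>::from(gW)),
      _["gb"] = wrap(arma::conv_to<arma::vec>::from(gb)));
}

// length-2, stride-2 max pooling; odd trailing element dropped
// [[Rcpp::export]]
NumericVector cpp_maxpool_forward(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int L = dims[0], C = dims[1], B = dims[2];
  const int L2 = L / 2;
  arma::cube xd(x.begin(), L, C, B, false);
  NumericVector out(static_cast<R_xlen_t>(L2) * C * B);
  out.attr("dim") = IntegerVector::create(L2, C, B);
  arma::cube od(out.begin(), L2, C, B, false);
  for (int s = 0; s < B; ++s) {
    const double* xp = xd.slice_memptr(s);
    double* op = od.slice_memptr(s);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (arma::uword)c * L;
      double* oc = op + (arma::uword)c * L2;
      for (int t = 0; t < L2; ++t)
        oc[t] = std::max(xc[2 * t], xc[2 * t + 1]);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector x, NumericVector gout) {
  IntegerVector dims = x.attr("dim");
  const int L = dims[0], C = dims[1], B = dims[2];
  const int L2 = L / 2;
  arma::cube xd(x.begin(), L, C, B, false);
  arma::cube gd(gout.begin(), L2, C, B, false);
  NumericVector gx(static_cast<R_xlen_t>(L) * C * B);
  gx.attr("dim") = IntegerVector::create(L, C, B);
  arma::cube gxd(gx.begin(), L, C, B, false);
  for (int s = 0; s < B; ++s) {
    const double* xp = xd.slice_memptr(s);
    const double* gp = gd.slice_memptr(s);
    double* op = gxd.slice_memptr(s);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (arma::uword)c * L;
      const double* gc = gp + (arma::uword)c * L2;
      double* oc = op + (arma::uword)c * L;
      for (int t = 0; t < L2; ++t) {
        if (xc[2 * t] >= xc[2 * t + 1]) oc[2 * t] = gc[t];
        else oc[2 * t + 1] = gc[t];
      }
    }
  }
  return gx;
}
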