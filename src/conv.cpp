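#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Same-padded 2D convolution (cross-correlation) primitives used by the
// delineation and classification networks. Feature maps are H x W x C cubes;
// weights are (k*k*Cin) x Cout matrices whose rows are ordered channel-major,
// then kernel column offset, then kernel row offset (di fastest). The R side
// relies on this ordering when initialising and updating weights.
//
// Arithmetic runs in single precision: the networks are trained with noisy
// stochastic gradients, so float accuracy is ample, and sgemm roughly
// doubles throughput over dgemm on these shapes.

static arma::fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  arma::fcube out(d[0], d[1], d.size() > 2 ? d[2] : 1);
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

static arma::fmat as_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

static NumericVector cube_to_r(const arma::fcube& x) {
  NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static arma::fmat im2col_same(const arma::fcube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  arma::fmat cols(H * W, k * k * C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        float* dst = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const float* src = &x(0, sj, c);
          for (int i = i0; i < i1; ++i) dst[(size_t)j * H + i] = src[i + di];
        }
        ++col;
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericMatrix& w,
                         const NumericVector& b, const int k) {
  const arma::fcube xc = as_fcube(x);
  const arma::fmat wf = as_fmat(w);
  const int H = xc.n_rows, W = xc.n_cols, Cout = wf.n_cols;
  arma::fmat out = im2col_same(xc, k) * wf;
  arma::frowvec bf(Cout);
  for (int c = 0; c < Cout; ++c) bf[c] = (float)b[c];
  out.each_row() += bf;
  arma::fcube oc(out.memptr(), H, W, Cout, false, true);
  return cube_to_r(oc);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const NumericVector& x, const NumericMatrix& w,
                const NumericVector& dout, const int k) {
  const arma::fcube xc = as_fcube(x);
  const arma::fmat wf = as_fmat(w);
  const arma::fcube dc = as_fcube(dout);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices, r = k / 2;
  const int Cout = dc.n_slices;
  const arma::fmat cols = im2col_same(xc, k);
  const arma::fmat doutm(const_cast<float*>(dc.memptr()), H * W, Cout,
                         false, true);
  arma::fmat dw = cols.t() * doutm;
  arma::fmat dcols = doutm * wf.t();
  arma::fcube dx(H, W, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const float* src = dcols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          float* dst = &dx(0, sj, c);
          for (int i = i0; i < i1; ++i) dst[i + di] += src[(size_t)j * H + i];
        }
        ++col;
      }
    }
  }
  NumericMatrix dwr(dw.n_rows, dw.n_cols);
  std::copy(dw.memptr(), dw.memptr() + dw.n_elem, dwr.begin());
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) db[c] = arma::accu(doutm.col(c));
  return List::create(_["dx"] = cube_to_r(dx), _["dw"] = dwr, _["db"] = db);
}
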