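// Convolution kernels for the compact CNN: im2col assembly in C++ with the
// heavy products delegated to BLAS through Armadillo. Tensor layout matches
// the R side: (maps, height, width, batch), column-major, with the weight
// matrix (c_out x c_in*k_h*k_w) whose kernel columns are ordered input
// channel fastest, then kernel height, then kernel width.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Geom {
  int c_in, h, w, n, kh, kw, sh, sw, ph, pw;
  int hp, wp, oh, ow, ckk, per;
  explicit Geom(const IntegerVector& xdim, const IntegerVector& par) {
    c_in = xdim[0]; h = xdim[1]; w = xdim[2]; n = xdim[3];
    kh = par[0]; kw = par[1]; sh = par[2]; sw = par[3];
    ph = par[4]; pw = par[5];
    hp = h + 2 * ph;
    wp = w + 2 * pw;
    oh = (hp - kh) / sh + 1;
    ow = (wp - kw) / sw + 1;
    ckk = c_in * kh * kw;
    per = oh * ow;
  }
};

// copy one sample into its zero-padded buffer (c_in x hp x wp)
void pad_sample(const double* xs, arma::vec& xp, const Geom& g) {
  xp.zeros();
  for (int ww = 0; ww < g.w; ++ww) {
    const double* src = xs + static_cast<size_t>(ww) * g.c_in * g.h;
    double* dst = xp.memptr() +
      (static_cast<size_t>(ww + g.pw) * g.hp + g.ph) * g.c_in;
    std::copy(src, src + static_cast<size_t>(g.c_in) * g.h, dst);
  }
}

// assemble the column matrix of one padded sample
void im2col(const arma::vec& xp, arma::mat& col, const Geom& g) {
  for (int kwi = 0; kwi < g.kw; ++kwi)
    for (int khi = 0; khi < g.kh; ++khi) {
      const int r0 = g.c_in * (khi + g.kh * kwi);
      for (int owi = 0; owi < g.ow; ++owi) {
        const int ww = owi * g.sw + kwi;
        for (int ohi = 0; ohi < g.oh; ++ohi) {
          const int hh = ohi * g.sh + khi;
          const double* src = xp.memptr() +
            (static_cast<size_t>(ww) * g.hp + hh) * g.c_in;
          double* dst = col.colptr(ohi + g.oh * owi) + r0;
          std::copy(src, src + g.c_in, dst);
        }
      }
    }
}

// scatter-add the column-matrix gradient back into the padded sample
void col2im_add(const arma::mat& dcol, arma::vec& dxp, const Geom& g) {
  for (int kwi = 0; kwi < g.kw; ++kwi)
    for (int khi = 0; khi < g.kh; ++khi) {
      const int r0 = g.c_in * (khi + g.kh * kwi);
      for (int owi = 0; owi < g.ow; ++owi) {
        const int ww = owi * g.sw + kwi;
        for (int ohi = 0; ohi < g.oh; ++ohi) {
          const int hh = ohi * g.sh + khi;
          double* dst = dxp.memptr() +
            (static_cast<size_t>(ww) * g.hp + hh) * g.c_in;
          const double* src = dcol.colptr(ohi + g.oh * owi) + r0;
          for (int c = 0; c < g.c_in; ++c) dst[c] += src[c];
        }
      }
    }
}

void unpad_sample(const arma::vec& dxp, double* dxs, const Geom& g) {
  for (int ww = 0; ww < g.w; ++ww) {
    const double* src = dxp.memptr() +
      (static_cast<size_t>(ww + g.pw) * g.hp + g.ph) * g.c_in;
    double* dst = dxs + static_cast<size_t>(ww) * g.c_in * g.h;
    std::copy(src, src + static_cast<size_t>(g.c_in) * g.h, dst);
  }
}

}  // namespace

// [[Rcpp::export(rng = false)]]
NumericVector conv_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                           const arma::mat& W, const arma::vec& b,
                           const IntegerVector& par) {
  const Geom g(xdim, par);
  const int c_out = W.n_rows;
  NumericVector y(static_cast<R_xlen_t>(c_out) * g.per * g.n);
  arma::vec xp(static_cast<size_t>(g.c_in) * g.hp * g.wp);
  arma::mat col(g.ckk, g.per);
  for (int s = 0; s < g.n; ++s) {
    pad_sample(x.begin() + static_cast<size_t>(s) * g.c_in * g.h * g.w, xp, g);
    im2col(xp, col, g);
    arma::mat ys(y.begin() + static_cast<size_t>(s) * c_out * g.per,
                 c_out, g.per, false, true);
    ys = W * col;
    ys.each_col() += b;
  }
  y.attr("dim") = IntegerVector::create(c_out, g.oh, g.ow, g.n);
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv_bwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                  const NumericVector& dy, const arma::mat& W,
                  const IntegerVector& par) {
  const Geom g(xdim, par);
  const int c_out = W.n_rows;
  NumericVector dx(x.size());
  arma::mat dW(c_out, g.ckk, arma::fill::zeros);
  arma::vec db(c_out, arma::fill::zeros);
  arma::vec xp(static_cast<size_t>(g.c_in) * g.hp * g.wp);
  arma::vec dxp(xp.n_elem);
  arma::mat col(g.ckk, g.per);
  for (int s = 0; s < g.n; ++s) {
    pad_sample(x.begin() + static_cast<size_t>(s) * g.c_in * g.h * g.w, xp, g);
    im2col(xp, col, g);
    const arma::mat dys(const_cast<double*>(dy.begin()) +
                          static_cast<size_t>(s) * c_out * g.per,
                        c_out, g.per, false, true);
    dW += dys * col.t();
    db += arma::sum(dys, 1);
    arma::mat dcol = W.t() * dys;
    dxp.zeros();
    col2im_add(dcol, dxp, g);
    unpad_sample(dxp, dx.begin() + static_cast<size_t>(s) * g.c_in * g.h * g.w,
                 g);
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
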