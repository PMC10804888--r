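// Convolution and pooling kernels for the CNN engine.
//
// Arrays follow R's column-major layout with dims (h, w, c, n):
// x[i + h*(j + w*(k + c*m))] is sample m, channel k, row i, column j.
// Convolutions are "valid" (no padding); pooling stride equals pool size.
//
// Samples are processed in blocks: im2col patches for a block of samples are
// packed into one matrix so each BLAS product is large enough to run at full
// throughput. The block size caps the working set at a few tens of MB.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int block_samples(int K, int O) {
  // target <= ~48 MB for the patch matrix
  double per_sample = (double)K * O * 8.0;
  int b = (int)(48.0 * 1024 * 1024 / std::max(per_sample, 1.0));
  return std::max(1, std::min(b, 64));
}

static inline void im2col_into(const double *x, int h, int w, int c,
                               int kh, int kw, int sh, int sw,
                               int oh, int ow, arma::mat &P, int col0) {
  // fills P columns [col0, col0 + oh*ow) for one sample
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      double *col = P.colptr(col0 + oi + oh * oj);
      int r = 0;
      for (int kc = 0; kc < c; ++kc) {
        const double *plane = x + (size_t)h * w * kc;
        for (int kj = 0; kj < kw; ++kj) {
          const double *src = plane + (size_t)h * (oj * sw + kj) + oi * sh;
          for (int ki = 0; ki < kh; ++ki) col[r++] = src[ki];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector wgt, IntegerVector wdim,
                        NumericVector b, int sh, int sw) {
  const int h = xdim[0], w = xdim[1], c = xdim[2], n = xdim[3];
  const int kh = wdim[0], kw = wdim[1], f = wdim[3];
  if (wdim[2] != c) stop("kernel depth does not match input channels");
  if (kh > h || kw > w) stop("kernel larger than input");
  const int oh = (h - kh) / sh + 1, ow = (w - kw) / sw + 1;
  const int K = kh * kw * c, O = oh * ow;
  const int B = block_samples(K, O);

  arma::mat W(const_cast<double *>(wgt.begin()), K, f, false, true);
  NumericVector out((R_xlen_t)O * f * n);
  out.attr("dim") = IntegerVector::create(oh, ow, f, n);
  arma::mat P(K, (size_t)O * B);
  const arma::rowvec bias(const_cast<double *>(b.begin()), f, false, true);

  for (int m0 = 0; m0 < n; m0 += B) {
    const int nb = std::min(B, n - m0);
    for (int m = 0; m < nb; ++m)
      im2col_into(x.begin() + (size_t)h * w * c * (m0 + m),
                  h, w, c, kh, kw, sh, sw, oh, ow, P, m * O);
    arma::mat Pb(P.memptr(), K, (size_t)O * nb, false, true);
    arma::mat Ob = Pb.t() * W;             // (O*nb) x f
    Ob.each_row() += bias;
    // scatter per-sample O x f slabs into the (O, f, sample) layout
    for (int m = 0; m < nb; ++m) {
      arma::mat dst(out.begin() + (size_t)O * f * (m0 + m), O, f, false, true);
      dst = Ob.rows((size_t)m * O, (size_t)(m + 1) * O - 1);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, IntegerVector xdim,
               NumericVector wgt, IntegerVector wdim,
               NumericVector dout, int sh, int sw, bool need_dx) {
  const int h = xdim[0], w = xdim[1], c = xdim[2], n = xdim[3];
  const int kh = wdim[0], kw = wdim[1], f = wdim[3];
  const int oh = (h - kh) / sh + 1, ow = (w - kw) / sw + 1;
  const int K = kh * kw * c, O = oh * ow;
  const int B = block_samples(K, O);

  arma::mat W(const_cast<double *>(wgt.begin()), K, f, false, true);
  arma::mat dW(K, f, arma::fill::zeros);
  arma::rowvec db(f, arma::fill::zeros);
  NumericVector dx(need_dx ? (R_xlen_t)h * w * c * n : 1);
  if (need_dx) dx.attr("dim") = xdim;
  arma::mat P(K, (size_t)O * B), dOb((size_t)O * B, f);

  for (int m0 = 0; m0 < n; m0 += B) {
    const int nb = std::min(B, n - m0);
    for (int m = 0; m < nb; ++m) {
      im2col_into(x.begin() + (size_t)h * w * c * (m0 + m),
                  h, w, c, kh, kw, sh, sw, oh, ow, P, m * O);
      arma::mat src(const_cast<double *>(dout.begin()) +
                      (size_t)O * f * (m0 + m), O, f, false, true);
      dOb.rows((size_t)m * O, (size_t)(m + 1) * O - 1) = src;
    }
    // P columns are contiguous so a column view is safe; dOb needs a row
    // view because its leading dimension is the full block height
    arma::mat Pb(P.memptr(), K, (size_t)O * nb, false, true);
    dW += Pb * dOb.head_rows((size_t)O * nb);
    db += arma::sum(dOb.head_rows((size_t)O * nb), 0);
    if (!need_dx) continue;
    arma::mat dP = W * dOb.head_rows((size_t)O * nb).t();  // K x (O*nb)
    for (int m = 0; m < nb; ++m) {
      // col2im scatter-add for one sample
      double *dxm = dx.begin() + (size_t)h * w * c * (m0 + m);
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          const double *col = dP.colptr((size_t)m * O + oi + oh * oj);
          int r = 0;
          for (int kc = 0; kc < c; ++kc) {
            double *plane = dxm + (size_t)h * w * kc;
            for (int kj = 0; kj < kw; ++kj) {
              double *dst = plane + (size_t)h * (oj * sw + kj) + oi * sh;
              for (int ki = 0; ki < kh; ++ki) dst[ki] += col[r++];
            }
          }
        }
      }
    }
  }
  NumericVector dWv(dW.begin(), dW.end());
  dWv.attr("dim") = wdim;
  return List::create(_["dw"] = dWv,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, IntegerVector xdim, int ph, int pw) {
  const int h = xdim[0], w = xdim[1], c = xdim[2], n = xdim[3];
  const int oh = h / ph, ow = w / pw;
  if (oh < 1 || ow < 1) stop("pool window larger than input");
  NumericVector out((R_xlen_t)oh * ow * c * n);
  out.attr("dim") = IntegerVector::create(oh, ow, c, n);
  IntegerVector idx(out.size());  // 1-based linear index into x of each max

  for (int m = 0; m < n; ++m) {
    for (int k = 0; k < c; ++k) {
      const size_t base = (size_t)h * w * (k + (size_t)c * m);
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          double best = R_NegInf;
          size_t bestix = 0;
          for (int pj = 0; pj < pw; ++pj) {
            const size_t colbase = base + (size_t)h * (oj * pw + pj) + oi * ph;
            for (int pi = 0; pi < ph; ++pi) {
              double v = x[colbase + pi];
              if (v > best) { best = v; bestix = colbase + pi; }
            }
          }
          size_t oix = (size_t)oi + oh * ((size_t)oj + ow * (k + (size_t)c * m));
          out[oix] = best;
          idx[oix] = (int)bestix + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector dout, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i] - 1] += dout[i];
  return dx;
}
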