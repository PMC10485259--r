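// Low-level numerical kernels: batched n-D convolution (im2col + BLAS),
// nearest-neighbour upsampling, differentiable image warping, moving-window
// sums and separable Gaussian smoothing.  All tensors are plain R arrays in
// column-major order; batched feature maps use layout (C, n1..nd, B).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int dilation, int pad) {
  int eff = dilation * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// Build the im2col matrix (C*k^d rows, prod(out)*B columns) for an isotropic
// kernel of size k per axis.  Out-of-bounds taps contribute zeros.
template <typename eT>
static void im2col_fill(const double* x, const IntegerVector& xd,
                        int k, int stride, int dilation, int pad,
                        arma::Mat<eT>& col) {
  const int nd = xd.size() - 2;         // spatial dimensionality
  const int C = xd[0];
  const int B = xd[xd.size() - 1];
  int nsp[3] = {1, 1, 1}, osp[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) {
    nsp[a] = xd[a + 1];
    osp[a] = out_size(nsp[a], k, stride, dilation, pad);
  }
  const R_xlen_t nvox_in = (R_xlen_t)nsp[0] * nsp[1] * nsp[2];
  const R_xlen_t nvox_out = (R_xlen_t)osp[0] * osp[1] * osp[2];
  const int k3 = (nd == 3) ? k : 1;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)C * nvox_in * b;
    R_xlen_t cidx = (R_xlen_t)nvox_out * b;
    for (int o3 = 0; o3 < osp[2]; ++o3)
      for (int o2 = 0; o2 < osp[1]; ++o2)
        for (int o1 = 0; o1 < osp[0]; ++o1, ++cidx) {
          eT* dst = col.colptr(cidx);
          const int base1 = o1 * stride - pad;
          const int base2 = o2 * stride - pad;
          const int base3 = o3 * stride - pad;
          int row = 0;
          for (int t3 = 0; t3 < k3; ++t3) {
            const int i3 = (nd == 3) ? base3 + dilation * t3 : 0;
            const bool ok3 = (nd < 3) || (i3 >= 0 && i3 < nsp[2]);
            for (int t2 = 0; t2 < k; ++t2) {
              const int i2 = base2 + dilation * t2;
              const bool ok2 = ok3 && i2 >= 0 && i2 < nsp[1];
              for (int t1 = 0; t1 < k; ++t1, row += C) {
                const int i1 = base1 + dilation * t1;
                if (ok2 && i1 >= 0 && i1 < nsp[0]) {
                  const double* src =
                    xb + (R_xlen_t)C * (i1 + (R_xlen_t)nsp[0] * (i2 + (R_xlen_t)nsp[1] * i3));
                  for (int c = 0; c < C; ++c) dst[row + c] = (eT)src[c];
                } else {
                  std::fill(dst + row, dst + row + C, (eT)0);
                }
              }
            }
          }
        }
  }
}

// Scatter-add of a column matrix back onto the input grid (adjoint of im2col).
template <typename eT>
static void col2im_nd(const arma::Mat<eT>& col, double* dx,
                      const IntegerVector& xd,
                      int k, int stride, int dilation, int pad) {
  const int nd = xd.size() - 2;
  const int C = xd[0];
  const int B = xd[xd.size() - 1];
  int nsp[3] = {1, 1, 1}, osp[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) {
    nsp[a] = xd[a + 1];
    osp[a] = out_size(nsp[a], k, stride, dilation, pad);
  }
  const R_xlen_t nvox_in = (R_xlen_t)nsp[0] * nsp[1] * nsp[2];
  const R_xlen_t nvox_out = (R_xlen_t)osp[0] * osp[1] * osp[2];
  const int k3 = (nd == 3) ? k : 1;

  for (int b = 0; b < B; ++b) {
    double* xb = dx + (R_xlen_t)C * nvox_in * b;
    R_xlen_t cidx = (R_xlen_t)nvox_out * b;
    for (int o3 = 0; o3 < osp[2]; ++o3)
      for (int o2 = 0; o2 < osp[1]; ++o2)
        for (int o1 = 0; o1 < osp[0]; ++o1, ++cidx) {
          const eT* src = col.colptr(cidx);
          const int base1 = o1 * stride - pad;
          const int base2 = o2 * stride - pad;
          const int base3 = o3 * stride - pad;
          int row = 0;
          for (int t3 = 0; t3 < k3; ++t3) {
            const int i3 = (nd == 3) ? base3 + dilation * t3 : 0;
            const bool ok3 = (nd < 3) || (i3 >= 0 && i3 < nsp[2]);
            for (int t2 = 0; t2 < k; ++t2) {
              const int i2 = base2 + dilation * t2;
              const bool ok2 = ok3 && i2 >= 0 && i2 < nsp[1];
              for (int t1 = 0; t1 < k; ++t1, row += C) {
                const int i1 = base1 + dilation * t1;
                if (ok2 && i1 >= 0 && i1 < nsp[0]) {
                  double* dst =
                    xb + (R_xlen_t)C * (i1 + (R_xlen_t)nsp[0] * (i2 + (R_xlen_t)nsp[1] * i3));
                  for (int c = 0; c < C; ++c) dst[c] += src[row + c];
                }
              }
            }
          }
        }
  }
}

template <typename eT>
static List conv_fwd_t(NumericVector x, IntegerVector xdim, NumericMatrix W,
                       NumericVector bias, int k, int stride, int dilation,
                       int pad, bool keep_col, bool dbl) {
  const int nd = xdim.size() - 2;
  const int B = xdim[xdim.size() - 1];
  R_xlen_t nvox_out = 1;
  IntegerVector ydim(nd + 2);
  ydim[0] = W.nrow();
  for (int a = 0; a < nd; ++a) {
    ydim[a + 1] = out_size(xdim[a + 1], k, stride, dilation, pad);
    nvox_out *= ydim[a + 1];
  }
  ydim[nd + 1] = B;
  const R_xlen_t ncols = nvox_out * B;
  const int CK = W.ncol();

  // the im2col buffer lives in an R raw vector so it can be cached for the
  // backward pass without an extra copy
  RawVector colraw(sizeof(eT) * (R_xlen_t)CK * ncols);
  arma::Mat<eT> col(reinterpret_cast<eT*>(RAW(colraw)), CK, ncols,
                    false, true);
  im2col_fill<eT>(x.begin(), xdim, k, stride, dilation, pad, col);

  arma::Mat<eT> Wf(W.nrow(), CK);
  std::copy(W.begin(), W.end(), Wf.begin());
  arma::Mat<eT> Yf = Wf * col;
  arma::Col<eT> bf(bias.size());
  std::copy(bias.begin(), bias.end(), bf.begin());
  Yf.each_col() += bf;

  NumericVector y((R_xlen_t)W.nrow() * ncols);
  std::copy(Yf.begin(), Yf.end(), y.begin());
  y.attr("dim") = ydim;
  if (keep_col)
    return List::create(_["y"] = y, _["col"] = colraw,
                        _["ncols"] = (double)ncols, _["dbl"] = dbl);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, IntegerVector xdim, NumericMatrix W,
                  NumericVector bias, int k, int stride, int dilation,
                  int pad, bool keep_col, bool dbl) {
  if (dbl)
    return conv_fwd_t<double>(x, xdim, W, bias, k, stride, dilation, pad,
                              keep_col, dbl);
  return conv_fwd_t<float>(x, xdim, W, bias, k, stride, dilation, pad,
                           keep_col, dbl);
}

template <typename eT>
static List conv_bwd_t(RawVector colraw, double ncols_d, IntegerVector xdim,
                       NumericMatrix W, NumericVector dy, int k, int stride,
                       int dilation, int pad, bool need_dx) {
  const R_xlen_t ncols = (R_xlen_t)ncols_d;
  const int CK = W.ncol();
  const arma::Mat<eT> col(
      reinterpret_cast<eT*>(RAW(colraw)), CK, ncols, false, true);

  arma::Mat<eT> dYf(W.nrow(), ncols);
  std::copy(dy.begin(), dy.end(), dYf.begin());

  arma::Mat<eT> dWf = dYf * col.t();
  NumericMatrix dWr(W.nrow(), CK);
  std::copy(dWf.begin(), dWf.end(), dWr.begin());
  arma::Col<eT> dbf = arma::sum(dYf, 1);
  NumericVector db(dbf.n_elem);
  std::copy(dbf.begin(), dbf.end(), db.begin());

  List out = List::create(_["dW"] = dWr, _["db"] = db);
  if (need_dx) {
    arma::Mat<eT> Wf(W.nrow(), CK);
    std::copy(W.begin(), W.end(), Wf.begin());
    arma::Mat<eT> dcol = Wf.t() * dYf;
    NumericVector dx((R_xlen_t)std::accumulate(
        xdim.begin(), xdim.end(), (R_xlen_t)1, std::multiplies<R_xlen_t>()));
    std::fill(dx.begin(), dx.end(), 0.0);
    col2im_nd<eT>(dcol, dx.begin(), xdim, k, stride, dilation, pad);
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(RawVector colraw, double ncols_d, IntegerVector xdim,
                  NumericMatrix W, NumericVector dy, int k, int stride,
                  int dilation, int pad, bool need_dx, bool dbl) {
  if (dbl)
    return conv_bwd_t<double>(colraw, ncols_d, xdim, W, dy, k, stride,
                              dilation, pad, need_dx);
  return conv_bwd_t<float>(colraw, ncols_d, xdim, W, dy, k, stride,
                           dilation, pad, need_dx);
}

// Nearest-neighbour upsampling by a factor of 2 along every spatial axis.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int nd = xdim.size() - 2;
  const int C = xdim[0], B = xdim[xdim.size() - 1];
  int nsp[3] = {1, 1, 1}, msp[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) { nsp[a] = xdim[a + 1]; msp[a] = 2 * nsp[a]; }
  const R_xlen_t nin = (R_xlen_t)nsp[0] * nsp[1] * nsp[2];
  const R_xlen_t nout = (R_xlen_t)msp[0] * msp[1] * msp[2];
  NumericVector y((R_xlen_t)C * nout * B);
  IntegerVector ydim(nd + 2);
  ydim[0] = C;
  for (int a = 0; a < nd; ++a) ydim[a + 1] = msp[a];
  ydim[nd + 1] = B;
  const int m3 = (nd == 3) ? msp[2] : 1;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (R_xlen_t)C * nin * b;
    double* yb = y.begin() + (R_xlen_t)C * nout * b;
    for (int j3 = 0; j3 < m3; ++j3)
      for (int j2 = 0; j2 < msp[1]; ++j2)
        for (int j1 = 0; j1 < msp[0]; ++j1) {
          const double* src = xb + (R_xlen_t)C *
            ((j1 >> 1) + (R_xlen_t)nsp[0] * ((j2 >> 1) + (R_xlen_t)nsp[1] * (j3 >> 1)));
          double* dst = yb + (R_xlen_t)C *
            (j1 + (R_xlen_t)msp[0] * (j2 + (R_xlen_t)msp[1] * j3));
          std::copy(src, src + C, dst);
        }
  }
  y.attr("dim") = ydim;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector ydim) {
  const int nd = ydim.size() - 2;
  const int C = ydim[0], B = ydim[ydim.size() - 1];
  int msp[3] = {1, 1, 1}, nsp[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) { msp[a] = ydim[a + 1]; nsp[a] = msp[a] / 2; }
  const R_xlen_t nin = (R_xlen_t)nsp[0] * nsp[1] * nsp[2];
  const R_xlen_t nout = (R_xlen_t)msp[0] * msp[1] * msp[2];
  NumericVector dx((R_xlen_t)C * nin * B);
  IntegerVector xdim(nd + 2);
  xdim[0] = C;
  for (int a = 0; a < nd; ++a) xdim[a + 1] = nsp[a];
  xdim[nd + 1] = B;
  const int m3 = (nd == 3) ? msp[2] : 1;
  for (int b = 0; b < B; ++b) {
    const double* yb = dy.begin() + (R_xlen_t)C * nout * b;
    double* xb = dx.begin() + (R_xlen_t)C * nin * b;
    for (int j3 = 0; j3 < m3; ++j3)
      for (int j2 = 0; j2 < msp[1]; ++j2)
        for (int j1 = 0; j1 < msp[0]; ++j1) {
          const double* src = yb + (R_xlen_t)C *
            (j1 + (R_xlen_t)msp[0] * (j2 + (R_xlen_t)msp[1] * j3));
          double* dst = xb + (R_xlen_t)C *
            ((j1 >> 1) + (R_xlen_t)nsp[0] * ((j2 >> 1) + (R_xlen_t)nsp[1] * (j3 >> 1)));
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
  }
  dx.attr("dim") = xdim;
  return dx;
}

static inline double clampd(double s, double lo, double hi) {
  return s < lo ? lo : (s > hi ? hi : s);
}

// Backward warp of a single-channel image by a displacement field stored as
// (d, n1..nd): out[x] = img[x + u(x)] with border clamping.  method 0 =
// linear, 1 = nearest.  d in {1,2,3}.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, IntegerVector idim,
                       NumericVector field, int method) {
  const int nd = idim.size();
  int n[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) n[a] = idim[a];
  const R_xlen_t nvox = (R_xlen_t)n[0] * n[1] * n[2];
  NumericVector out(nvox);
  out.attr("dim") = idim;
  const double* u = field.begin();
  const double* im = img.begin();

  R_xlen_t v = 0;
  for (int i3 = 0; i3 < n[2]; ++i3)
    for (int i2 = 0; i2 < n[1]; ++i2)
      for (int i1 = 0; i1 < n[0]; ++i1, ++v) {
        double s[3] = {(double)i1, (double)i2, (double)i3};
        for (int a = 0; a < nd; ++a)
          s[a] = clampd(s[a] + u[a + nd * v], 0.0, n[a] - 1.0);
        if (method == 1) {
          int p[3];
          for (int a = 0; a < 3; ++a)
            p[a] = (int)clampd(std::floor(s[a] + 0.5), 0.0, n[a] - 1.0);
          out[v] = im[p[0] + (R_xlen_t)n[0] * (p[1] + (R_xlen_t)n[1] * p[2])];
        } else {
          int f[3] = {0, 0, 0};
          double w[3] = {0.0, 0.0, 0.0};
          for (int a = 0; a < nd; ++a) {
            f[a] = (int)std::floor(s[a]);
            if (f[a] > n[a] - 2) f[a] = n[a] - 2;
            if (f[a] < 0) f[a] = 0;
            w[a] = s[a] - f[a];
          }
          double acc = 0.0;
          const int c3 = (nd >= 3) ? 2 : 1;
          const int c2 = (nd >= 2) ? 2 : 1;
          for (int t3 = 0; t3 < c3; ++t3)
            for (int t2 = 0; t2 < c2; ++t2)
              for (int t1 = 0; t1 < 2; ++t1) {
                double wt = (t1 ? w[0] : 1.0 - w[0]);
                if (nd >= 2) wt *= (t2 ? w[1] : 1.0 - w[1]);
                if (nd >= 3) wt *= (t3 ? w[2] : 1.0 - w[2]);
                if (wt == 0.0) continue;
                acc += wt * im[(f[0] + t1) +
                               (R_xlen_t)n[0] * ((f[1] + t2) +
                               (R_xlen_t)n[1] * (f[2] + t3))];
              }
          out[v] = acc;
        }
      }
  return out;
}

// Gradient of sum(dout * warp_linear(img, field)) with respect to the field.
// Clamped coordinates get zero derivative along the clamped axis.
// [[Rcpp::export]]
NumericVector cpp_warp_bwd_field(NumericVector img, IntegerVector idim,
                                 NumericVector field, NumericVector dout) {
  const int nd = idim.size();
  int n[3] = {1, 1, 1};
  for (int a = 0; a < nd; ++a) n[a] = idim[a];
  const R_xlen_t nvox = (R_xlen_t)n[0] * n[1] * n[2];
  NumericVector df((R_xlen_t)nd * nvox);
  IntegerVector fdim(nd + 1);
  fdim[0] = nd;
  for (int a = 0; a < nd; ++a) fdim[a + 1] = n[a];
  df.attr("dim") = fdim;
  const double* u = field.begin();
  const double* im = img.begin();

  R_xlen_t v = 0;
  for (int i3 = 0; i3 < n[2]; ++i3)
    for (int i2 = 0; i2 < n[1]; ++i2)
      for (int i1 = 0; i1 < n[0]; ++i1, ++v) {
        const double g = dout[v];
        if (g == 0.0) continue;
        double raw[3] = {(double)i1, (double)i2, (double)i3};
        double s[3] = {raw[0], raw[1], raw[2]};
        bool interior[3] = {true, true, true};
        for (int a = 0; a < nd; ++a) {
          double t = raw[a] + u[a + nd * v];
          interior[a] = (t > 0.0 && t < n[a] - 1.0);
          s[a] = clampd(t, 0.0, n[a] - 1.0);
        }
        int f[3] = {0, 0, 0};
        double w[3] = {0.0, 0.0, 0.0};
        for (int a = 0; a < nd; ++a) {
          f[a] = (int)std::floor(s[a]);
          if (f[a] > n[a] - 2) f[a] = n[a] - 2;
          if (f[a] < 0) f[a] = 0;
          w[a] = s[a] - f[a];
        }
        const int c3 = (nd >= 3) ? 2 : 1;
        const int c2 = (nd >= 2) ? 2 : 1;
        double grad[3] = {0.0, 0.0, 0.0};
        for (int t3 = 0; t3 < c3; ++t3)
          for (int t2 = 0; t2 < c2; ++t2)
            for (int t1 = 0; t1 < 2; ++t1) {
              const double val = im[(f[0] + t1) +
                                    (R_xlen_t)n[0] * ((f[1] + t2) +
                                    (R_xlen_t)n[1] * (f[2] + t3))];
              const double w1 = t1 ? w[0] : 1.0 - w[0];
              const double d1 = t1 ? 1.0 : -1.0;
              double w2 = 1.0, d2 = 0.0, w3 = 1.0, d3 = 0.0;
              if (nd >= 2) { w2 = t2 ? w[1] : 1.0 - w[1]; d2 = t2 ? 1.0 : -1.0; }
              if (nd >= 3) { w3 = t3 ? w[2] : 1.0 - w[2]; d3 = t3 ? 1.0 : -1.0; }
              grad[0] += d1 * w2 * w3 * val;
              if (nd >= 2) grad[1] += w1 * d2 * w3 * val;
              if (nd >= 3) grad[2] += w1 * w2 * d3 * val;
            }
        for (int a = 0; a < nd; ++a)
          if (interior[a]) df[a + nd * v] += g * grad[a];
      }
  return df;
}

// Moving-window sum of width w (odd) along every axis in turn, zero outside.
// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, IntegerVector dims, int w) {
  const int nd = dims.size();
  const int h = w / 2;
  R_xlen_t ntot = 1;
  for (int a = 0; a < nd; ++a) ntot *= dims[a];
  NumericVector cur = clone(x);
  std::vector<double> line, acc;
  for (int a = 0; a < nd; ++a) {
    const int n = dims[a];
    R_xlen_t stride = 1;
    for (int q = 0; q < a; ++q) stride *= dims[q];
    const R_xlen_t nlines = ntot / n;
    line.assign(n, 0.0);
    acc.assign(n + 1, 0.0);
    for (R_xlen_t l = 0; l < nlines; ++l) {
      // base index of this line
      const R_xlen_t low = l % stride;
      const R_xlen_t high = l / stride;
      const R_xlen_t base = low + high * stride * n;
      double* p = cur.begin() + base;
      acc[0] = 0.0;
      for (int i = 0; i < n; ++i) acc[i + 1] = acc[i] + p[(R_xlen_t)i * stride];
      for (int i = 0; i < n; ++i) {
        const int lo = std::max(0, i - h);
        const int hi = std::min(n - 1, i + h);
        line[i] = acc[hi + 1] - acc[lo];
      }
      for (int i = 0; i < n; ++i) p[(R_xlen_t)i * stride] = line[i];
    }
  }
  cur.attr("dim") = dims;
  return cur;
}

// Separable correlation with a symmetric 1-D kernel along every axis,
// replicate padding at the borders (used for Gaussian smoothing).
// [[Rcpp::export]]
NumericVector cpp_sepconv_replicate(NumericVector x, IntegerVector dims,
                                    NumericVector kernel) {
  const int nd = dims.size();
  const int klen = kernel.size();
  const int h = klen / 2;
  R_xlen_t ntot = 1;
  for (int a = 0; a < nd; ++a) ntot *= dims[a];
  NumericVector cur = clone(x);
  std::vector<double> line;
  for (int a = 0; a < nd; ++a) {
    const int n = dims[a];
    R_xlen_t stride = 1;
    for (int q = 0; q < a; ++q) stride *= dims[q];
    const R_xlen_t nlines = ntot / n;
    line.assign(n, 0.0);
    for (R_xlen_t l = 0; l < nlines; ++l) {
      const R_xlen_t low = l % stride;
      const R_xlen_t high = l / stride;
      const R_xlen_t base = low + high * stride * n;
      double* p = cur.begin() + base;
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int t = -h; t <= h; ++t) {
          int j = i + t;
          if (j < 0) j = 0;
          if (j > n - 1) j = n - 1;
          s += kernel[t + h] * p[(R_xlen_t)j * stride];
        }
        line[i] = s;
      }
      for (int i = 0; i < n; ++i) p[(R_xlen_t)i * stride] = line[i];
    }
  }
  cur.attr("dim") = dims;
  return cur;
}

// Leaky rectification, slope in (0, 1): y = x for x >= 0, slope * x below.
// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0.0) p[i] *= slope;
  return y;
}

// dy scaled by the local slope, recovered from the sign of the output y.
// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector dy, NumericVector y, double slope) {
  NumericVector dx = clone(dy);
  double* p = dx.begin();
  const double* q = y.begin();
  const R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (q[i] < 0.0) p[i] *= slope;
  return dx;
}
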