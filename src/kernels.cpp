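// Dense 2D CNN kernels (double precision) used by the modified U-Net.
// Tensor layout everywhere: column-major R arrays (H, W, C, N).
// Convolution weights: matrix (Cin*k*k) x Cout, row index q = ((c*k)+dy)*k+dx.
// Transposed-conv weights: matrix Cin x (Cout*4), col index q = co*4 + dy*2+dx.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static inline IntegerVector make4i(int a, int b, int c, int d) {
  IntegerVector v((size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double *x, int H, int W, int C, int k, int pad,
                   arma::mat &cols) {
  // cols: (H*W) x (C*k*k)
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double *plane = x + (size_t)c * HW;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        int q = (c * k + dy) * k + dx;
        double *dst = cols.colptr(q);
        for (int w = 0; w < W; ++w) {
          int w2 = w + dx - pad;
          double *dcol = dst + (size_t)w * H;
          if (w2 < 0 || w2 >= W) {
            std::fill(dcol, dcol + H, 0.0);
            continue;
          }
          const double *scol = plane + (size_t)w2 * H;
          for (int h = 0; h < H; ++h) {
            int h2 = h + dy - pad;
            dcol[h] = (h2 < 0 || h2 >= H) ? 0.0 : scol[h2];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &cols, int H, int W, int C, int k, int pad,
                   double *dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double *plane = dx + (size_t)c * HW;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx_ = 0; dx_ < k; ++dx_) {
        int q = (c * k + dy) * k + dx_;
        const double *src = cols.colptr(q);
        for (int w = 0; w < W; ++w) {
          int w2 = w + dx_ - pad;
          if (w2 < 0 || w2 >= W) continue;
          double *dcol = plane + (size_t)w2 * H;
          const double *scol = src + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            int h2 = h + dy - pad;
            if (h2 < 0 || h2 >= H) continue;
            dcol[h2] += scol[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         int k, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Cout = w.ncol();
  if ((int)w.nrow() != C * k * k) stop("conv weight shape mismatch");
  const int HW = H * W;
  NumericVector out = make4(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat cols(HW, C * k * k);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, cols);
    arma::mat y = cols * wm;  // (HW x Cout)
    for (int co = 0; co < Cout; ++co) y.col(co) += b[co];
    std::copy(y.begin(), y.end(), out.begin() + (size_t)n * HW * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int k, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Cout = w.ncol();
  const int HW = H * W;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector dx = make4(H, W, C, N);
  arma::mat dw(C * k * k, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(HW, C * k * k);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, cols);
    arma::mat dym(dy.begin() + (size_t)n * HW * Cout, HW, Cout, false);
    dw += cols.t() * dym;
    db += arma::sum(dym, 0).t();
    arma::mat dcols = dym * wm.t();  // (HW x C*k*k)
    col2im(dcols, H, W, C, k, pad, dx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(dw.n_rows, dw.n_cols, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool input height/width must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx = make4i(Ho, Wo, C, N);  // 0..3: dy + 2*dx
  const int HW = H * W, HWo = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + (size_t)(n * C + c) * HW;
      double *q = y.begin() + (size_t)(n * C + c) * HWo;
      int *qi = idx.begin() + (size_t)(n * C + c) * HWo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          int best = 0;
          double bv = p[(size_t)(2 * w) * H + 2 * h];
          for (int dx_ = 0; dx_ < 2; ++dx_) {
            for (int dy = 0; dy < 2; ++dy) {
              double v = p[(size_t)(2 * w + dx_) * H + 2 * h + dy];
              if (v > bv) { bv = v; best = dy + 2 * dx_; }
            }
          }
          q[(size_t)w * Ho + h] = bv;
          qi[(size_t)w * Ho + h] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           int H, int W) {
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make4(H, W, C, N);
  const int HW = H * W, HWo = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *g = dy.begin() + (size_t)(n * C + c) * HWo;
      const int *qi = idx.begin() + (size_t)(n * C + c) * HWo;
      double *p = dx.begin() + (size_t)(n * C + c) * HW;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          int best = qi[(size_t)w * Ho + h];
          int dy_ = best % 2, dx_ = best / 2;
          p[(size_t)(2 * w + dx_) * H + 2 * h + dy_] += g[(size_t)w * Ho + h];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector convT2_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if ((int)w.nrow() != C || w.ncol() % 4 != 0) stop("convT weight shape mismatch");
  int Cout = w.ncol() / 4;
  int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  NumericVector out = make4(Ho, Wo, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * HW * C, HW, C, false);
    arma::mat yb = xm * wm;  // (HW x Cout*4)
    double *o = out.begin() + (size_t)n * HWo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double *plane = o + (size_t)co * HWo;
      std::fill(plane, plane + HWo, b[co]);
      for (int dx_ = 0; dx_ < 2; ++dx_) {
        for (int dy = 0; dy < 2; ++dy) {
          const double *src = yb.colptr(co * 4 + dy * 2 + dx_);
          for (int w_ = 0; w_ < W; ++w_) {
            double *dcol = plane + (size_t)(2 * w_ + dx_) * Ho;
            const double *scol = src + (size_t)w_ * H;
            for (int h = 0; h < H; ++h) dcol[2 * h + dy] += scol[h];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List convT2_bwd(NumericVector x, NumericMatrix w, NumericVector dy) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int Cout = w.ncol() / 4;
  int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector dx = make4(H, W, C, N);
  arma::mat dw(C, Cout * 4, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat gb(HW, Cout * 4);
  for (int n = 0; n < N; ++n) {
    const double *g = dy.begin() + (size_t)n * HWo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double *plane = g + (size_t)co * HWo;
      double s = 0;
      for (int i = 0; i < HWo; ++i) s += plane[i];
      db[co] += s;
      for (int dx_ = 0; dx_ < 2; ++dx_) {
        for (int dy_ = 0; dy_ < 2; ++dy_) {
          double *dst = gb.colptr(co * 4 + dy_ * 2 + dx_);
          for (int w_ = 0; w_ < W; ++w_) {
            const double *scol = plane + (size_t)(2 * w_ + dx_) * Ho;
            double *dcol = dst + (size_t)w_ * H;
            for (int h = 0; h < H; ++h) dcol[h] = scol[2 * h + dy_];
          }
        }
      }
    }
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * HW * C, HW, C, false);
    dw += xm.t() * gb;
    arma::mat dxm = gb * wm.t();  // (HW x C)
    std::copy(dxm.begin(), dxm.end(), dx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(dw.n_rows, dw.n_cols, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
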