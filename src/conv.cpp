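// Same-padding 2D convolution kernels for feature stacks, via im2col + GEMM.
// Feature stacks are H x W x C x T arrays (column-major, R layout); kernels
// are k x k x Cin x Cout with odd k. Used by the unrolled reconstruction
// backbone; gradients are exact adjoints of the forward pass.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill P (H*W x k*k*Cin) with patches of frame t of x (zero padding).
// Column index r = ki + k*kj + k*k*ci matches the column-major layout of the
// kernel array, so the GEMM is P * reshape(w, k*k*Cin, Cout).
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& P) {
  const int pad = (k - 1) / 2;
  const long HW = (long)H * W;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (long)ci * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * ci;
        double* col = P.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int js = j + kj - pad;
          if (js < 0 || js >= W) {
            for (int i = 0; i < H; ++i) col[i + (long)H * j] = 0.0;
            continue;
          }
          const double* src = xc + (long)H * js;
          for (int i = 0; i < H; ++i) {
            const int is = i + ki - pad;
            col[i + (long)H * j] = (is < 0 || is >= H) ? 0.0 : src[is];
          }
        }
      }
    }
  }
}

static void get_dims(const NumericVector& x, int& H, int& W, int& C, int& T) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("feature stack must be a 4-d array (H, W, C, T)");
  H = d[0]; W = d[1]; C = d[2]; T = d[3];
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, T;
  get_dims(x, H, W, Cin, T);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("kernel must be a 4-d array (k, k, Cin, Cout)");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("kernel dims do not match input");
  if (b.size() != Cout) stop("bias length must equal Cout");

  const long HW = (long)H * W;
  arma::mat Wm(w.begin(), (long)k * k * Cin, Cout, false, true);
  arma::mat P(HW, (long)k * k * Cin);
  NumericVector out(HW * Cout * T);
  out.attr("dim") = IntegerVector::create(H, W, Cout, T);

  for (int t = 0; t < T; ++t) {
    im2col(x.begin() + (long)t * HW * Cin, H, W, Cin, k, P);
    arma::mat Y(out.begin() + (long)t * HW * Cout, HW, Cout, false, true);
    Y = P * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return out;
}

// Gradients of the convolution: given upstream dy (H x W x Cout x T),
// returns dx (like x), dw (like w), db (Cout).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  bool need_dx = true) {
  int H, W, Cin, T;
  get_dims(x, H, W, Cin, T);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  IntegerVector dyd = dy.attr("dim");
  if (dyd[0] != H || dyd[1] != W || dyd[2] != Cout || dyd[3] != T)
    stop("dy dims do not match");

  const long HW = (long)H * W;
  arma::mat P(HW, (long)k * k * Cin);
  arma::mat dWm((long)k * k * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  NumericVector dx;
  arma::mat Wrot;
  if (need_dx) {
    dx = NumericVector(HW * Cin * T);
    dx.attr("dim") = IntegerVector::create(H, W, Cin, T);
    // rotated kernel for the input gradient: dx = corr(dy, rot180(w), swap io)
    Wrot.set_size((long)k * k * Cout, Cin);
    const double* wp = w.begin();
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const double v = wp[ki + (long)k * kj + (long)k * k * ci
                                + (long)k * k * Cin * co];
            Wrot((k - 1 - ki) + k * (k - 1 - kj) + k * k * co, ci) = v;
          }
  }
  arma::mat Pdy;
  if (need_dx) Pdy.set_size(HW, (long)k * k * Cout);

  for (int t = 0; t < T; ++t) {
    arma::mat dY((double*)dy.begin() + (long)t * HW * Cout, HW, Cout,
                 false, true);
    im2col(x.begin() + (long)t * HW * Cin, H, W, Cin, k, P);
    dWm += P.t() * dY;
    db += arma::sum(dY, 0).t();
    if (need_dx) {
      im2col(dy.begin() + (long)t * HW * Cout, H, W, Cout, k, Pdy);
      arma::mat dX(dx.begin() + (long)t * HW * Cin, HW, Cin, false, true);
      dX = Pdy * Wrot;
    }
  }

  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
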