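// Low-level kernels: 3x3 convolution forward/backward (im2col + GEMM) for
// the encoder-decoder network, and 3-D connected-component labelling for
// the segmentation stage. Kernel size is fixed at 3x3 with zero padding 1;
// stride 1 or 2 as used by the strided encoder.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::cube asCube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  arma::cube c(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
  return c;
}

static arma::mat im2col3(const arma::cube& x, int stride, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(Ho * (arma::uword)Wo, 9 * (arma::uword)C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int col = c * 9 + kj * 3 + ki;
        double* dst = out.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - 1;
          const bool jin = (j >= 0 && j < W);
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - 1;
            dst[(arma::uword)oj * Ho + oi] =
              (jin && i >= 0 && i < H) ? x(i, j, c) : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// y[Ho,Wo,Cout] = conv3x3(x[H,W,Cin], w[9*Cin,Cout]) + b, zero pad 1
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, const arma::mat& w,
                           const arma::vec& b, int stride) {
  arma::cube xc = asCube(x);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Ho = (H + 2 - 3) / stride + 1, Wo = (W + 2 - 3) / stride + 1;
  if ((int)w.n_rows != 9 * (int)xc.n_slices)
    stop("weight rows do not match 9 * input channels");
  arma::mat cols = im2col3(xc, stride, Ho, Wo);
  arma::mat y = cols * w;
  y.each_row() += b.t();
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, (int)w.n_cols);
  return out;
}

// gradients of the same convolution; dy has dim (Ho,Wo,Cout)
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, const arma::mat& w, NumericVector dy,
                  int stride) {
  arma::cube xc = asCube(x);
  arma::cube dyc = asCube(dy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = dyc.n_rows, Wo = dyc.n_cols, Co = dyc.n_slices;
  arma::mat cols = im2col3(xc, stride, Ho, Wo);
  arma::mat dyMat(dyc.memptr(), (arma::uword)Ho * Wo, Co, false, true);
  arma::mat dW = cols.t() * dyMat;
  arma::vec db = arma::sum(dyMat, 0).t();
  arma::mat dCols = dyMat * w.t();        // (Ho*Wo, 9*C)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int col = c * 9 + kj * 3 + ki;
        const double* src = dCols.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - 1;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - 1;
            if (i < 0 || i >= H) continue;
            dx(i, j, c) += src[(arma::uword)oj * Ho + oi];
          }
        }
      }
    }
  }
  NumericVector dxOut(dx.begin(), dx.end());
  dxOut.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dx"] = dxOut, _["dW"] = dW, _["db"] = db);
}

// Connected-component labelling of a 3-d logical mask, 6- or 26-connectivity.
// Labels are assigned in scan order starting at 1; 0 is background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be a 3-d array");
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(n, 0);
  labels.attr("dim") = d;
  const int* msk = LOGICAL(mask);
  int* lab = INTEGER(labels);

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manhattan = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        off.push_back(dy);
        off.push_back(dx);
        off.push_back(dz);
      }
  const size_t nOff = off.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (msk[s] != TRUE || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % n1);
      const int j = (int)((cur / n1) % n2);
      const int k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (size_t t = 0; t < nOff; t += 3) {
        const int ii = i + off[t];
        if (ii < 0 || ii >= n1) continue;
        const int jj = j + off[t + 1];
        if (jj < 0 || jj >= n2) continue;
        const int kk = k + off[t + 2];
        if (kk < 0 || kk >= n3) continue;
        const R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (msk[nb] == TRUE && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// 6-neighbourhood binary erosion / dilation (face-connected), zero boundary
static LogicalVector morph6(LogicalVector mask, bool erode) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be a 3-d array");
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  LogicalVector out((R_xlen_t)n1 * n2 * n3);
  out.attr("dim") = d;
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t s = base + i;
        bool c = m[s] == TRUE;
        bool up = (i > 0) && m[s - 1] == TRUE;
        bool dn = (i < n1 - 1) && m[s + 1] == TRUE;
        bool le = (j > 0) && m[s - n1] == TRUE;
        bool ri = (j < n2 - 1) && m[s + n1] == TRUE;
        bool bk = (k > 0) && m[s - (R_xlen_t)n1 * n2] == TRUE;
        bool fr = (k < n3 - 1) && m[s + (R_xlen_t)n1 * n2] == TRUE;
        if (erode)
          o[s] = (c && up && dn && le && ri && bk && fr) ? TRUE : FALSE;
        else
          o[s] = (c || up || dn || le || ri || bk || fr) ? TRUE : FALSE;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode6(LogicalVector mask) { return morph6(mask, true); }

// [[Rcpp::export]]
LogicalVector cpp_dilate6(LogicalVector mask) { return morph6(mask, false); }
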