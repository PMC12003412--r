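#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are H x W x C arrays in R's column-major layout.
// im2col unrolls stride-1 dilated convolution patches into a matrix with one
// row per output pixel (row index i + Hout * j) and one column per
// (channel, kernel-row, kernel-col) tap, so convolution becomes a single
// BLAS matmul on the R side. col2im is its exact adjoint, used for the
// input gradient.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector input, int H, int W, int C,
                         int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  if (Hout <= 0 || Wout <= 0)
    stop("input smaller than the dilated kernel support");
  NumericMatrix cols(Hout * Wout, kh * kw * C);
  const double* in = input.begin();
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int colidx = c * kh * kw + ki * kw + kj;
        double* dst = &cols(0, colidx);
        for (int j = 0; j < Wout; ++j) {
          const int jj = j - pad + kj * dil;
          for (int i = 0; i < Hout; ++i) {
            const int ii = i - pad + ki * dil;
            double v = 0.0;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W)
              v = in[ii + H * (jj + W * c)];
            dst[i + Hout * j] = v;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcols, int H, int W, int C,
                         int kh, int kw, int pad, int dil) {
  const int Hout = H + 2 * pad - dil * (kh - 1);
  const int Wout = W + 2 * pad - dil * (kw - 1);
  NumericVector dinput(H * W * C);
  double* out = dinput.begin();
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int colidx = c * kh * kw + ki * kw + kj;
        const double* src = &dcols(0, colidx);
        for (int j = 0; j < Wout; ++j) {
          const int jj = j - pad + kj * dil;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int ii = i - pad + ki * dil;
            if (ii < 0 || ii >= H) continue;
            out[ii + H * (jj + W * c)] += src[i + Hout * j];
          }
        }
      }
    }
  }
  dinput.attr("dim") = IntegerVector::create(H, W, C);
  return dinput;
}

// 2x2 max pooling, stride 2, ceil mode (ragged edge pools the remainder).
// Returns the pooled map and the flat argmax index of each output cell for
// the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector input, int H, int W, int C) {
  const int Hout = (H + 1) / 2;
  const int Wout = (W + 1) / 2;
  NumericVector out(Hout * Wout * C);
  IntegerVector argmax(Hout * Wout * C);
  const double* in = input.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        double best = R_NegInf;
        int bestidx = -1;
        for (int dj = 0; dj < 2; ++dj) {
          const int jj = 2 * j + dj;
          if (jj >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di;
            if (ii >= H) continue;
            const int idx = ii + H * (jj + W * c);
            if (in[idx] > best) { best = in[idx]; bestidx = idx; }
          }
        }
        const int oidx = i + Hout * (j + Wout * c);
        out[oidx] = best;
        argmax[oidx] = bestidx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return List::create(_["out"] = out, _["argmax"] = argmax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector argmax,
                               int H, int W, int C) {
  NumericVector dinput(H * W * C);
  for (int k = 0; k < dout.size(); ++k)
    dinput[argmax[k]] += dout[k];
  dinput.attr("dim") = IntegerVector::create(H, W, C);
  return dinput;
}
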