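// 3x3 same-padding convolution primitives for the reference U-Net.
// The hot path is im2col assembly; the matrix product itself goes
// through the BLAS R is linked against (via RcppArmadillo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// offsets in the same order as R's .offsets3: di fastest, -1..1 each
static const int DI[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int DJ[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

// [[Rcpp::export(name = ".conv3ForwardC")]]
List conv3_forward(const arma::cube& x, const arma::mat& W,
                   const arma::vec& b, bool relu, bool want_col) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const arma::uword HW = H * Wd;
  arma::mat col(HW, 9 * C);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int o = 0; o < 9; ++o) {
      const int di = DI[o], dj = DJ[o];
      double* dst = col.colptr(o * C + c);
      for (arma::uword j = 0; j < Wd; ++j) {
        const long js = (long)j + dj;
        double* dcol = dst + j * H;
        if (js < 0 || js >= (long)Wd) {
          std::fill(dcol, dcol + H, 0.0);
          continue;
        }
        const double* src = s.colptr(js);
        const long lo = (di < 0) ? 1 : 0;          // first dst row written
        const long hi = (di > 0) ? H - 1 : H;      // one past last
        if (di < 0) dcol[0] = 0.0;
        if (di > 0) dcol[H - 1] = 0.0;
        std::memcpy(dcol + lo, src + lo + di, (hi - lo) * sizeof(double));
      }
    }
  }
  arma::mat z = col * W;
  z.each_row() += b.t();
  if (relu) z.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::cube out(z.memptr(), H, Wd, W.n_cols);
  List res = List::create(Named("out") = out);
  if (want_col) res["col"] = col;
  return res;
}

// scatter-add the column gradient back onto the input grid
// [[Rcpp::export(name = ".col2im3C")]]
arma::cube col2im3(const arma::mat& dcol, int H, int Wd, int C) {
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  const arma::uword HW = (arma::uword)H * Wd;
  for (int c = 0; c < C; ++c) {
    arma::mat& s = dx.slice(c);
    for (int o = 0; o < 9; ++o) {
      const int di = DI[o], dj = DJ[o];
      const double* src = dcol.colptr((arma::uword)o * C + c);
      for (int j = 0; j < Wd; ++j) {
        const long js = (long)j + dj;
        if (js < 0 || js >= (long)Wd) continue;
        double* dsl = s.colptr(js);
        const double* scol = src + (arma::uword)j * H;
        const long lo = (di < 0) ? 1 : 0;
        const long hi = (di > 0) ? H - 1 : H;
        for (long i = lo; i < hi; ++i) dsl[i + di] += scol[i];
      }
    }
  }
  return dx;
}
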