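// Compiled kernels for the batched feature-map representation: 3x3
// zero-padded convolution (spatial shape preserved) and per-image group
// normalisation. X is a (B*H*W) x C matrix: image blocks contiguous,
// pixels within an image in column-major H x W order. Conv weights are
// (9*C) x Cout with the 9 taps ordered (dc, dr) in {-1,0,1}^2, dr
// fastest. The convolution runs as one GEMM per tap on shifted
// contiguous row ranges of X (no im2col patch matrix), with exact
// fixups where a shifted view crosses a column or image boundary.
// GEMMs go through Armadillo (system BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Accumulate Y += shift_{(dr,dc)}(X) * Mk over the valid (zero-padded)
// region, using one large GEMM on a contiguous row range per image plus
// small gathered fixups for the column-boundary rows the big view reads
// across, and per-row handling of the few rows trimmed at the global
// matrix edges.
static void tapAccum(const arma::mat& X, const arma::mat& Mk, int dr,
                     int dc, int B, int H, int W, arma::mat& Y) {
  const int npix = H * W;
  const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
  if (c1 <= c0) return;
  const long s = (long)dc * H + dr;
  const int C = X.n_cols;
  const int Cout = Mk.n_cols;
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * npix + (long)c0 * H;
    const long n1 = (long)(c1 - c0) * H;
    const long in0 = base + s;
    long trimHead = 0, trimTail = 0;
    if (in0 < 0) trimHead = -in0;
    if (in0 + n1 > (long)X.n_rows) trimTail = in0 + n1 - X.n_rows;
    const long nBig = n1 - trimHead - trimTail;
    if (nBig > 0) {
      Y.rows(base + trimHead, base + trimHead + nBig - 1) +=
        X.rows(in0 + trimHead, in0 + trimHead + nBig - 1) * Mk;
    }
    // rows excluded from the big GEMM: compute exactly, with bounds checks
    for (long t = base; t < base + trimHead; ++t) {
      const long rel = t - (long)b * npix;
      const int c = rel / H, r = rel % H;
      const int ri = r + dr, ci = c + dc;
      if (ri < 0 || ri >= H || ci < 0 || ci >= W) continue;
      Y.row(t) += X.row((long)b * npix + (long)ci * H + ri) * Mk;
    }
    for (long t = base + n1 - trimTail; t < base + n1; ++t) {
      const long rel = t - (long)b * npix;
      const int c = rel / H, r = rel % H;
      const int ri = r + dr, ci = c + dc;
      if (ri < 0 || ri >= H || ci < 0 || ci >= W) continue;
      Y.row(t) += X.row((long)b * npix + (long)ci * H + ri) * Mk;
    }
    // subtract the contributions the big GEMM wrongly added at column
    // boundaries (vertical taps read across adjacent columns)
    if (dr != 0 && nBig > 0) {
      const int rbad = (dr == 1) ? H - 1 : 0;
      std::vector<long> rows;
      rows.reserve(c1 - c0);
      for (int c = c0; c < c1; ++c) {
        const long t = (long)b * npix + (long)c * H + rbad;
        if (t < base + trimHead || t >= base + n1 - trimTail) continue;
        rows.push_back(t);
      }
      const int n = rows.size();
      if (n > 0) {
        arma::mat buf(n, C);
        for (int j = 0; j < C; ++j) {
          const double* xc = X.colptr(j);
          double* bc = buf.colptr(j);
          for (int i = 0; i < n; ++i) bc[i] = xc[rows[i] + s];
        }
        arma::mat out = buf * Mk;
        for (int j = 0; j < Cout; ++j) {
          double* yc = Y.colptr(j);
          const double* oc = out.colptr(j);
          for (int i = 0; i < n; ++i) yc[rows[i]] -= oc[i];
        }
      }
    }
  }
}

// dWk += shift(X)^T * dY over the valid region, same decomposition
static void tapDW(const arma::mat& X, const arma::mat& dY, int dr, int dc,
                  int B, int H, int W, arma::mat& dWk) {
  const int npix = H * W;
  const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
  if (c1 <= c0) return;
  const long s = (long)dc * H + dr;
  const int C = X.n_cols;
  const int Cout = dY.n_cols;
  for (int b = 0; b < B; ++b) {
    const long base = (long)b * npix + (long)c0 * H;
    const long n1 = (long)(c1 - c0) * H;
    const long in0 = base + s;
    long trimHead = 0, trimTail = 0;
    if (in0 < 0) trimHead = -in0;
    if (in0 + n1 > (long)X.n_rows) trimTail = in0 + n1 - X.n_rows;
    const long nBig = n1 - trimHead - trimTail;
    if (nBig > 0) {
      dWk += X.rows(in0 + trimHead, in0 + trimHead + nBig - 1).t() *
        dY.rows(base + trimHead, base + trimHead + nBig - 1);
    }
    for (long t = base; t < base + trimHead; ++t) {
      const long rel = t - (long)b * npix;
      const int c = rel / H, r = rel % H;
      const int ri = r + dr, ci = c + dc;
      if (ri < 0 || ri >= H || ci < 0 || ci >= W) continue;
      dWk += X.row((long)b * npix + (long)ci * H + ri).t() * dY.row(t);
    }
    for (long t = base + n1 - trimTail; t < base + n1; ++t) {
      const long rel = t - (long)b * npix;
      const int c = rel / H, r = rel % H;
      const int ri = r + dr, ci = c + dc;
      if (ri < 0 || ri >= H || ci < 0 || ci >= W) continue;
      dWk += X.row((long)b * npix + (long)ci * H + ri).t() * dY.row(t);
    }
    if (dr != 0 && nBig > 0) {
      const int rbad = (dr == 1) ? H - 1 : 0;
      std::vector<long> rows;
      rows.reserve(c1 - c0);
      for (int c = c0; c < c1; ++c) {
        const long t = (long)b * npix + (long)c * H + rbad;
        if (t < base + trimHead || t >= base + n1 - trimTail) continue;
        rows.push_back(t);
      }
      const int n = rows.size();
      if (n > 0) {
        arma::mat bufX(n, C), bufY(n, Cout);
        for (int j = 0; j < C; ++j) {
          const double* xc = X.colptr(j);
          double* bc = bufX.colptr(j);
          for (int i = 0; i < n; ++i) bc[i] = xc[rows[i] + s];
        }
        for (int j = 0; j < Cout; ++j) {
          const double* yc = dY.colptr(j);
          double* bc = bufY.colptr(j);
          for (int i = 0; i < n; ++i) bc[i] = yc[rows[i]];
        }
        dWk -= bufX.t() * bufY;
      }
    }
  }
}

// [[Rcpp::export(name = ".csConvFwd")]]
Rcpp::NumericMatrix csConvFwd(const arma::mat& X, int B, int H, int W,
                               const arma::mat& Wm, const arma::vec& bias) {
  const int C = X.n_cols;
  const int Cout = Wm.n_cols;
  Rcpp::NumericMatrix Yr(X.n_rows, Cout);
  arma::mat Y(Yr.begin(), X.n_rows, Cout, false, true);
  Y.each_row() = bias.t();
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      tapAccum(X, Wm.rows(k * C, (k + 1) * C - 1), dr, dc, B, H, W, Y);
      ++k;
    }
  return Yr;
}

// [[Rcpp::export(name = ".csConvBwd")]]
Rcpp::List csConvBwd(const arma::mat& X, const arma::mat& dY, int B,
                      int H, int W, const arma::mat& Wm, bool needX) {
  const int C = X.n_cols;
  const int Cout = Wm.n_cols;
  arma::mat dW(9 * C, Cout, arma::fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      arma::mat dWk(C, Cout, arma::fill::zeros);
      tapDW(X, dY, dr, dc, B, H, W, dWk);
      dW.rows(k * C, (k + 1) * C - 1) = dWk;
      ++k;
    }
  arma::rowvec db = arma::sum(dY, 0);
  Rcpp::NumericMatrix dXr(needX ? X.n_rows : 0, needX ? C : 0);
  if (needX) {
    arma::mat dX(dXr.begin(), X.n_rows, C, false, true);
    dX.zeros();
    k = 0;
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        // transpose of the forward: mirrored tap, transposed weights
        tapAccum(dY, Wm.rows(k * C, (k + 1) * C - 1).t(), -dr, -dc, B, H,
                 W, dX);
        ++k;
      }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dXr,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Per-image group normalisation (no affine part; that stays in R).
// Returns the normalised map Xh and the per-(image, group) inverse
// standard deviations.
// [[Rcpp::export(name = ".csGroupNormFwd")]]
Rcpp::List csGroupNormFwd(const arma::mat& X, int B, int g, double eps) {
  const int C = X.n_cols;
  const int cg = C / g;
  const int npix = X.n_rows / B;
  Rcpp::NumericMatrix Xhr(X.n_rows, C);
  arma::mat Xh(Xhr.begin(), X.n_rows, C, false, true);
  arma::mat istd(B, g);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < g; ++j) {
      double s = 0.0, s2 = 0.0;
      for (int ch = j * cg; ch < (j + 1) * cg; ++ch) {
        const double* x = X.colptr(ch) + (size_t)b * npix;
        for (int i = 0; i < npix; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      }
      const double n = (double)npix * cg;
      const double mu = s / n;
      double var = s2 / n - mu * mu;
      if (var < 0) var = 0;
      const double is = 1.0 / std::sqrt(var + eps);
      istd(b, j) = is;
      for (int ch = j * cg; ch < (j + 1) * cg; ++ch) {
        const double* x = X.colptr(ch) + (size_t)b * npix;
        double* xh = Xh.colptr(ch) + (size_t)b * npix;
        for (int i = 0; i < npix; ++i) xh[i] = (x[i] - mu) * is;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Xh") = Xhr,
                            Rcpp::Named("istd") = istd);
}

// Backward through the normalisation given dXh = dY * gamma.
// [[Rcpp::export(name = ".csGroupNormBwd")]]
Rcpp::NumericMatrix csGroupNormBwd(const arma::mat& dXh, const arma::mat& Xh,
                                   const arma::mat& istd, int B, int g) {
  const int C = dXh.n_cols;
  const int cg = C / g;
  const int npix = dXh.n_rows / B;
  Rcpp::NumericMatrix dXr(dXh.n_rows, C);
  arma::mat dX(dXr.begin(), dXh.n_rows, C, false, true);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < g; ++j) {
      double sd = 0.0, sdx = 0.0;
      for (int ch = j * cg; ch < (j + 1) * cg; ++ch) {
        const double* d = dXh.colptr(ch) + (size_t)b * npix;
        const double* xh = Xh.colptr(ch) + (size_t)b * npix;
        for (int i = 0; i < npix; ++i) { sd += d[i]; sdx += d[i] * xh[i]; }
      }
      const double n = (double)npix * cg;
      const double md = sd / n;
      const double mdx = sdx / n;
      const double is = istd(b, j);
      for (int ch = j * cg; ch < (j + 1) * cg; ++ch) {
        const double* d = dXh.colptr(ch) + (size_t)b * npix;
        const double* xh = Xh.colptr(ch) + (size_t)b * npix;
        double* o = dX.colptr(ch) + (size_t)b * npix;
        for (int i = 0; i < npix; ++i)
          o[i] = (d[i] - md - xh[i] * mdx) * is;
      }
    }
  }
  return dXr;
}
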