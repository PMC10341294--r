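// Low-level raster and network primitives.
//
// Feature maps are numeric 3-d arrays with dim (H, W, C), column-major as in
// R; a pixel (i, j) [0-based] has linear index i + j*H within a slice.
//
// Convolution weights for the 3x3 layers are (Cout, Cin*9) matrices; the
// column index for input channel cin and kernel offset (dy, dx) in {-1,0,1}
// is cin*9 + (dy+1)*3 + (dx+1).  Transposed-convolution (2x2, stride 2)
// weights are (Cout*4, Cin) matrices with row index co*4 + a*2 + b for
// output sub-position (a, b) in {0,1}^2.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(C * 9, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is < 0 || is >= H) continue;
            cols(r, i + j * H) = sl(is, js);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  if ((int)w.n_cols != (int)x.n_slices * 9)
    stop("conv3_forward: weight/input channel mismatch");
  arma::mat cols = im2col3(x);
  arma::mat y = w * cols;
  y.each_col() += b;
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.row(c).t(), H, W);
  return out;
}

// [[Rcpp::export]]
List conv3_backward(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  arma::mat dym(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = arma::vectorise(dy.slice(c)).t();
  arma::mat cols = im2col3(x);
  arma::mat dw = dym * cols.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcols = w.t() * dym;  // (Cin*9, H*W)
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    arma::mat& dsl = dx.slice(c);
    for (int dyk = -1; dyk <= 1; ++dyk) {
      for (int dxk = -1; dxk <= 1; ++dxk) {
        const int r = c * 9 + (dyk + 1) * 3 + (dxk + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dxk;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + dyk;
            if (is < 0 || is >= H) continue;
            dsl(is, js) += dcols(r, i + j * H);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2_forward: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int b = 0; b < 2; ++b) {
          for (int a = 0; a < 2; ++a) {
            const int ii = 2 * i + a, jj = 2 * j + b;
            const double v = sl(ii, jj);
            if (v > best) { best = v; bi = ii + jj * H; }
          }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& dy, const arma::ucube& idx,
                             int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* d = dx.slice_memptr(c);
    const arma::mat& g = dy.slice(c);
    const arma::umat& ix = idx.slice(c);
    for (arma::uword k = 0; k < g.n_elem; ++k) d[ix(k)] += g(k);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube upconv2_forward(const arma::cube& x, const arma::mat& u,
                           const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  if ((int)u.n_cols != Cin) stop("upconv2_forward: channel mismatch");
  const int Cout = u.n_rows / 4;
  arma::mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c) xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat ym = u * xm;  // (Cout*4, H*W)
  arma::cube out(2 * H, 2 * W, Cout);
  for (int c = 0; c < Cout; ++c) {
    arma::mat& sl = out.slice(c);
    sl.fill(b(c));
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        const int r = c * 4 + a * 2 + bb;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            sl(2 * i + a, 2 * j + bb) += ym(r, i + j * H);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List upconv2_backward(const arma::cube& x, const arma::mat& u,
                      const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = u.n_rows / 4;
  arma::mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c) xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat dyg(Cout * 4, H * W);
  arma::vec db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const arma::mat& g = dy.slice(c);
    db(c) = arma::accu(g);
    for (int a = 0; a < 2; ++a)
      for (int bb = 0; bb < 2; ++bb) {
        const int r = c * 4 + a * 2 + bb;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dyg(r, i + j * H) = g(2 * i + a, 2 * j + bb);
      }
  }
  arma::mat du = dyg * xm.t();
  arma::mat dxm = u.t() * dyg;
  arma::cube dx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = arma::reshape(dxm.row(c).t(), H, W);
  return List::create(_["dx"] = dx, _["du"] = du, _["db"] = db);
}

// Connected-component labeling of a 0/1 mask (BFS flood fill).
// connectivity: 4 or 8.  Labels are 1..K in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int n4i[] = {-1, 1, 0, 0}, n4j[] = {0, 0, -1, 1};
  const int n8i[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            n8j[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* ni = (connectivity == 4) ? n4i : n8i;
  const int* nj = (connectivity == 4) ? n4j : n8j;
  const int nn = connectivity;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int k = 0; k < nn; ++k) {
          const int ii = ci + ni[k], jj = cj + nj[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Two-pass chamfer distance from every pixel to the nearest pixel of the
// target set (set == 1).  Axial steps cost `wa`, diagonal steps `wd`:
// (1,1) gives the Chebyshev metric, (3,4)/3 a quasi-Euclidean one.
// Pixels of the set itself get 0; if the set is empty all distances are Inf.
// [[Rcpp::export]]
NumericMatrix chamfer_distance(const IntegerMatrix& set, double wa, double wd) {
  const int H = set.nrow(), W = set.ncol();
  NumericMatrix d(H, W);
  const double INF = R_PosInf;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d(i, j) = set(i, j) != 0 ? 0.0 : INF;
  // forward: neighbours above / left
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = d(i, j);
      if (i > 0) v = std::min(v, d(i - 1, j) + wa);
      if (j > 0) v = std::min(v, d(i, j - 1) + wa);
      if (i > 0 && j > 0) v = std::min(v, d(i - 1, j - 1) + wd);
      if (i < H - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + wd);
      d(i, j) = v;
    }
  }
  // backward: neighbours below / right
  for (int j = W - 1; j >= 0; --j) {
    for (int i = H - 1; i >= 0; --i) {
      double v = d(i, j);
      if (i < H - 1) v = std::min(v, d(i + 1, j) + wa);
      if (j < W - 1) v = std::min(v, d(i, j + 1) + wa);
      if (i < H - 1 && j < W - 1) v = std::min(v, d(i + 1, j + 1) + wd);
      if (i > 0 && j < W - 1) v = std::min(v, d(i - 1, j + 1) + wd);
      d(i, j) = v;
    }
  }
  return d;
}
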