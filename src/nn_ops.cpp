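// Minimal conv-net primitives for the FCN-8s segmentation model.
// Tensors are R arrays dim c(H, W, C) == arma::cube(H, W, C).
// Conv weights are matrices (kh*kw*C) x K with row index ((c*kh + dr)*kw + dc);
// transposed-conv weights are 4-D arrays dim c(k, k, C_in, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(kh * kw * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dr = 0; dr < kh; ++dr) {
      for (int dc = 0; dc < kw; ++dc) {
        const int ridx = (c * kh + dr) * kw + dc;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dc - pad;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dr - pad;
            if (hs < 0 || hs >= H) continue;
            col(ridx, (size_t)h + (size_t)H * w) = x(hs, ws, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& wmat,
                    const arma::vec& b, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int K = wmat.n_cols;
  arma::mat col = im2col(x, kh, kw, pad);
  arma::mat y = wmat.t() * col;          // K x (H*W)
  y.each_col() += b;
  arma::cube out(H, W, K);
  for (int k = 0; k < K; ++k)
    out.slice(k) = arma::reshape(y.row(k), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::cube& x, const arma::mat& wmat,
              const arma::cube& dy, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = wmat.n_cols;
  arma::mat dy_mat(K, (size_t)H * W);
  for (int k = 0; k < K; ++k)
    dy_mat.row(k) = arma::vectorise(dy.slice(k)).t();
  arma::mat col = im2col(x, kh, kw, pad);
  arma::mat dW = col * dy_mat.t();
  arma::vec db = arma::sum(dy_mat, 1);
  arma::mat dcol = wmat * dy_mat;        // (kh*kw*C) x (H*W)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dr = 0; dr < kh; ++dr) {
      for (int dc = 0; dc < kw; ++dc) {
        const int ridx = (c * kh + dr) * kw + dc;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dc - pad;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dr - pad;
            if (hs < 0 || hs >= H) continue;
            dx(hs, ws, c) += dcol(ridx, (size_t)h + (size_t)H * w);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Requires even H and W.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx((size_t)Ho * Wo * C);   // linear index into x of the max
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = -std::numeric_limits<double>::infinity();
        int best_i = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int hi = 2 * h + di, wi = 2 * w + dj;
            const double v = x(hi, wi, c);
            if (v > best) {
              best = v;
              best_i = hi + H * wi + H * W * c;
            }
          }
        }
        y(h, w, c) = best;
        idx[h + (size_t)Ho * w + (size_t)Ho * Wo * c] = best_i;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const IntegerVector& idx, const arma::cube& dy,
                       int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  double* px = dx.memptr();
  const double* pdy = dy.memptr();
  const size_t n = dy.n_elem;
  for (size_t i = 0; i < n; ++i) px[idx[i]] += pdy[i];
  return dx;
}

// Transposed convolution, kernel k x k, stride s, symmetric padding p.
// Output spatial size: (H-1)*s + k - 2*p.
// [[Rcpp::export(name = ".tconv_fwd")]]
arma::cube tconv_fwd(const arma::cube& x, const NumericVector& w,
                     const arma::vec& b, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], K = wd[3];
  if (Cin != C) stop("tconv weight/input channel mismatch");
  const int Ho = (H - 1) * s + k - 2 * p;
  const int Wo = (W - 1) * s + k - 2 * p;
  arma::cube y(Ho, Wo, K);
  for (int kk = 0; kk < K; ++kk) y.slice(kk).fill(b[kk]);
  const double* pw = REAL(w);
  for (int kk = 0; kk < K; ++kk) {
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const double xv = x(i, j, c);
          if (xv == 0.0) continue;
          for (int dj = 0; dj < k; ++dj) {
            const int wo = j * s - p + dj;
            if (wo < 0 || wo >= Wo) continue;
            for (int di = 0; di < k; ++di) {
              const int ho = i * s - p + di;
              if (ho < 0 || ho >= Ho) continue;
              y(ho, wo, kk) += xv * pw[di + (size_t)k * dj +
                                       (size_t)k * k * c +
                                       (size_t)k * k * Cin * kk];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv_bwd")]]
List tconv_bwd(const arma::cube& x, const NumericVector& w,
               const arma::cube& dy, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], K = wd[3];
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  NumericVector dw((size_t)k * k * Cin * K);
  dw.attr("dim") = wd;
  arma::vec db(K, arma::fill::zeros);
  const double* pw = REAL(w);
  double* pdw = REAL(dw);
  for (int kk = 0; kk < K; ++kk) {
    db[kk] = arma::accu(dy.slice(kk));
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = 0.0;
          const double xv = x(i, j, c);
          for (int dj = 0; dj < k; ++dj) {
            const int wo = j * s - p + dj;
            if (wo < 0 || wo >= Wo) continue;
            for (int di = 0; di < k; ++di) {
              const int ho = i * s - p + di;
              if (ho < 0 || ho >= Ho) continue;
              const double g = dy(ho, wo, kk);
              const size_t widx = di + (size_t)k * dj + (size_t)k * k * c +
                                  (size_t)k * k * Cin * kk;
              acc += g * pw[widx];
              pdw[widx] += g * xv;
            }
          }
          dx(i, j, c) += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Connected-component labeling of a binary matrix, 8- or 4-connectivity.
// Returns an integer matrix: 0 = off, components numbered from 1 in
// discovery (column-major scan) order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(r0 + H * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int r = cur % H, c = cur / H;
        for (int t = 0; t < nn; ++t) {
          const int rr = r + dr[t], cc = c + dc[t];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(rr + H * cc);
          }
        }
      }
    }
  }
  return lab;
}
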