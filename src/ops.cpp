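#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Row p of the patch matrix holds the receptive field of output pixel
// p = oi + oj * Ho, flattened in the same order as an R array of dim
// (kh, kw, C): column index k = di + dj * kh + c * kh * kw. Storing patches
// as rows keeps every write contiguous (column-major, p varies fastest) and
// makes the forward product  colT (P x K) * W (K x F)  land directly in the
// memory layout of an R array of dim (Ho, Wo, F). Out-of-bounds taps (zero
// padding) stay 0.
static mat im2colT(const cube &x, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat colT((uword)Ho * Wo, (uword)kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        double *dst = colT.colptr((uword)(di + dj * kh + c * kh * kw));
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + dj - pad;
          if (ij < 0 || ij >= W) continue;
          const double *src = xc + (size_t)ij * H;
          double *d = dst + (size_t)oj * Ho;
          const int ii0 = dj * 0 + di - pad;  // ii = oi*stride + di - pad
          if (stride == 1) {
            const int lo = std::max(0, -ii0), hi = std::min(Ho, H - ii0);
            for (int oi = lo; oi < hi; ++oi) d[oi] = src[oi + ii0];
          } else {
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ii0;
              if (ii >= 0 && ii < H) d[oi] = src[ii];
            }
          }
        }
      }
    }
  }
  return colT;
}

static void col2imT_acc(cube &dx, const mat &dcolT, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    double *xc = dx.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double *src = dcolT.colptr((uword)(di + dj * kh + c * kh * kw));
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + dj - pad;
          if (ij < 0 || ij >= W) continue;
          double *dstc = xc + (size_t)ij * H;
          const double *s = src + (size_t)oj * Ho;
          const int ii0 = di - pad;
          if (stride == 1) {
            const int lo = std::max(0, -ii0), hi = std::min(Ho, H - ii0);
            for (int oi = lo; oi < hi; ++oi) dstc[oi + ii0] += s[oi];
          } else {
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ii0;
              if (ii >= 0 && ii < H) dstc[ii] += s[oi];
            }
          }
        }
      }
    }
  }
}

// x: (H, W, C); wmat: (kh*kw*C, F); returns (Ho, Wo, F)
// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube &x, const arma::mat &wmat,
                          const arma::vec &bias, int kh, int kw, int stride,
                          int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  mat colT = im2colT(x, kh, kw, stride, pad, Ho, Wo);
  mat y = colT * wmat;           // P x F == cube (Ho, Wo, F) memory layout
  y.each_row() += bias.t();
  cube out(Ho, Wo, wmat.n_cols);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

static Rcpp::List conv_bwd_core(const mat &colT, const mat &wmat,
                                const cube &dy, int kh, int kw, int stride,
                                int pad, int H, int W, int C, bool want_dw,
                                bool want_dx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, F = dy.n_slices;
  const uword P = (uword)Ho * Wo;
  const mat dy_mat(const_cast<double *>(dy.memptr()), P, F, false, true);
  Rcpp::List res;
  if (want_dw) {
    res["dw"] = mat(colT.t() * dy_mat);       // (kh*kw*C) x F
    res["db"] = vec(sum(dy_mat, 0).t());
  }
  if (want_dx) {
    mat dcolT = dy_mat * wmat.t();            // P x (kh*kw*C)
    cube dx(H, W, C, fill::zeros);
    col2imT_acc(dx, dcolT, kh, kw, stride, pad, Ho, Wo);
    res["dx"] = dx;
  }
  return res;
}

// dy: (Ho, Wo, F). Returns list with dx and/or (dw (kh*kw*C x F), db)
// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::cube &x, const arma::mat &wmat,
                          const arma::cube &dy, int kh, int kw, int stride,
                          int pad, bool want_dw = true, bool want_dx = true) {
  mat colT;
  if (want_dw)
    colT = im2colT(x, kh, kw, stride, pad, dy.n_rows, dy.n_cols);
  return conv_bwd_core(colT, wmat, dy, kh, kw, stride, pad, x.n_rows,
                       x.n_cols, x.n_slices, want_dw, want_dx);
}


// Exhaustive integer-shift search. shift (dy,dx) means the reference tile is
// translated so that ref(r - dy, c - dx) is compared with uv(r, c); the score
// is the mean abs difference over the valid overlap. Ties prefer smaller
// |dy|+|dx|, then smaller dy, then smaller dx.
// [[Rcpp::export]]
Rcpp::List search_shift_cpp(const arma::mat &uv, const arma::mat &ref,
                            int radius) {
  const int H = uv.n_rows, W = uv.n_cols;
  double best = datum::inf;
  int bdy = 0, bdx = 0;
  for (int dy = -radius; dy <= radius; ++dy) {
    for (int dx = -radius; dx <= radius; ++dx) {
      const int r0 = std::max(0, dy), r1 = std::min(H, H + dy);
      const int c0 = std::max(0, dx), c1 = std::min(W, W + dx);
      if (r1 <= r0 || c1 <= c0) continue;
      const double score =
          accu(abs(uv.submat(r0, c0, r1 - 1, c1 - 1) -
                   ref.submat(r0 - dy, c0 - dx, r1 - 1 - dy, c1 - 1 - dx))) /
          ((double)(r1 - r0) * (c1 - c0));
      bool take = false;
      if (score < best) {
        take = true;
      } else if (score == best) {
        const int man = std::abs(dy) + std::abs(dx);
        const int bman = std::abs(bdy) + std::abs(bdx);
        if (man < bman || (man == bman && (dy < bdy || (dy == bdy && dx < bdx))))
          take = true;
      }
      if (take) {
        best = score;
        bdy = dy;
        bdx = dx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dy") = bdy, Rcpp::Named("dx") = bdx,
                            Rcpp::Named("score") = best);
}
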