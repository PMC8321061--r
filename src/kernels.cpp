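// Low-level numeric kernels: im2col/col2im for (dilated) convolution,
// ceil-mode max pooling, bilinear resampling with adjoint, generic
// coordinate remapping for geometric augmentation, and boundary-set
// Hausdorff distances.
//
// Array convention matches R: a (H, W, C) array maps onto arma::cube with
// n_rows = H, n_cols = W, n_slices = C. All coordinates passed from R are
// 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lay out image patches as columns: row index ki + kj*kh + c*kh*kw,
// column index oi + oj*oh (column-major over output positions). Taps
// falling outside the padded input read as zero.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int kh, int kw,
                     int stride, int dil, int pad_h, int pad_w,
                     int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(kh * kw * C, (arma::uword)oh * ow, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& slab = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        for (int oj = 0; oj < ow; ++oj) {
          const int jin = oj * stride - pad_w + kj * dil;
          if (jin < 0 || jin >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int iin = oi * stride - pad_h + ki * dil;
            if (iin < 0 || iin >= H) continue;
            cols(r, (arma::uword)oi + (arma::uword)oj * oh) = slab(iin, jin);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch columns back into an input-shaped
// gradient cube.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int dil,
                      int pad_h, int pad_w, int oh, int ow) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& slab = dx.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kj * kh + c * kh * kw;
        for (int oj = 0; oj < ow; ++oj) {
          const int jin = oj * stride - pad_w + kj * dil;
          if (jin < 0 || jin >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int iin = oi * stride - pad_h + ki * dil;
            if (iin < 0 || iin >= H) continue;
            slab(iin, jin) += cols(r, (arma::uword)oi + (arma::uword)oj * oh);
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with Caffe semantics: ceil-mode output size, windows clipped
// to the valid input region. Returns pooled values and 0-based argmax
// linear indices (i + j*H) per channel for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(const arma::cube& x, int k, int stride, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  arma::icube arg(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& slab = x.slice(c);
    for (int oj = 0; oj < ow; ++oj) {
      const int j0 = oj * stride;
      const int j1 = std::min(j0 + k, W);
      for (int oi = 0; oi < oh; ++oi) {
        const int i0 = oi * stride;
        const int i1 = std::min(i0 + k, H);
        double best = -std::numeric_limits<double>::infinity();
        int besti = i0, bestj = j0;
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            if (slab(i, j) > best) { best = slab(i, j); besti = i; bestj = j; }
        y(oi, oj, c) = best;
        arg(oi, oj, c) = besti + bestj * H;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dy, const arma::icube& arg,
                                int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& slab = dx.slice(c);
    for (arma::uword j = 0; j < dy.n_cols; ++j)
      for (arma::uword i = 0; i < dy.n_rows; ++i) {
        const long long a = arg(i, j, c);
        slab(a % H, a / H) += dy(i, j, c);
      }
  }
  return dx;
}

// Fixed bilinear resize with half-pixel centers (the non-learned upsampling
// used by the fusion sub-network).
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int oj = 0; oj < ow; ++oj) {
    double xs = (oj + 0.5) * sx - 0.5;
    xs = std::min(std::max(xs, 0.0), (double)W - 1);
    const int j0 = (int)std::floor(xs);
    const int j1 = std::min(j0 + 1, W - 1);
    const double wx = xs - j0;
    for (int oi = 0; oi < oh; ++oi) {
      double ys = (oi + 0.5) * sy - 0.5;
      ys = std::min(std::max(ys, 0.0), (double)H - 1);
      const int i0 = (int)std::floor(ys);
      const int i1 = std::min(i0 + 1, H - 1);
      const double wy = ys - i0;
      for (int c = 0; c < C; ++c) {
        const arma::mat& s = x.slice(c);
        y(oi, oj, c) =
          (1 - wy) * ((1 - wx) * s(i0, j0) + wx * s(i0, j1)) +
          wy       * ((1 - wx) * s(i1, j0) + wx * s(i1, j1));
      }
    }
  }
  return y;
}

// Adjoint of cpp_resize_bilinear: distribute output-gradient mass onto the
// four source taps of each output pixel.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_backward(const arma::cube& dy, int H, int W) {
  const int oh = dy.n_rows, ow = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int oj = 0; oj < ow; ++oj) {
    double xs = (oj + 0.5) * sx - 0.5;
    xs = std::min(std::max(xs, 0.0), (double)W - 1);
    const int j0 = (int)std::floor(xs);
    const int j1 = std::min(j0 + 1, W - 1);
    const double wx = xs - j0;
    for (int oi = 0; oi < oh; ++oi) {
      double ys = (oi + 0.5) * sy - 0.5;
      ys = std::min(std::max(ys, 0.0), (double)H - 1);
      const int i0 = (int)std::floor(ys);
      const int i1 = std::min(i0 + 1, H - 1);
      const double wy = ys - i0;
      for (int c = 0; c < C; ++c) {
        const double g = dy(oi, oj, c);
        dx(i0, j0, c) += (1 - wy) * (1 - wx) * g;
        dx(i0, j1, c) += (1 - wy) * wx * g;
        dx(i1, j0, c) += wy * (1 - wx) * g;
        dx(i1, j1, c) += wy * wx * g;
      }
    }
  }
  return dx;
}

static inline int reflect_index(int i, int n) {
  // Reflect-101 style border without repeating the edge sample twice.
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = std::abs(i) % period;
  return (i < n) ? i : period - i;
}

// Generic backward warp: output pixel (i,j) samples the source at
// (map_y(i,j), map_x(i,j)) (0-based, row/col). bilinear = false gives
// nearest-neighbour sampling (for masks). border: 0 = constant fill,
// 1 = reflect.
// [[Rcpp::export]]
arma::cube cpp_remap(const arma::cube& src, const arma::mat& map_y,
                     const arma::mat& map_x, bool bilinear,
                     int border, double fill) {
  const int H = src.n_rows, W = src.n_cols, C = src.n_slices;
  const int oh = map_y.n_rows, ow = map_y.n_cols;
  arma::cube y(oh, ow, C);
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const double ys = map_y(oi, oj), xs = map_x(oi, oj);
      if (!bilinear) {
        int i = (int)std::lround(ys), j = (int)std::lround(xs);
        if (i < 0 || i >= H || j < 0 || j >= W) {
          if (border == 1) { i = reflect_index(i, H); j = reflect_index(j, W); }
          else { for (int c = 0; c < C; ++c) y(oi, oj, c) = fill; continue; }
        }
        for (int c = 0; c < C; ++c) y(oi, oj, c) = src(i, j, c);
      } else {
        const int i0 = (int)std::floor(ys), j0 = (int)std::floor(xs);
        const double wy = ys - i0, wx = xs - j0;
        int ii[2] = { i0, i0 + 1 }, jj[2] = { j0, j0 + 1 };
        if (border == 1) {
          for (int t = 0; t < 2; ++t) {
            ii[t] = reflect_index(ii[t], H);
            jj[t] = reflect_index(jj[t], W);
          }
        }
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          const double wts[4] = { (1 - wy) * (1 - wx), (1 - wy) * wx,
                                  wy * (1 - wx), wy * wx };
          const int ti[4] = { ii[0], ii[0], ii[1], ii[1] };
          const int tj[4] = { jj[0], jj[1], jj[0], jj[1] };
          for (int t = 0; t < 4; ++t) {
            if (wts[t] == 0.0) continue;
            double v;
            if (ti[t] < 0 || ti[t] >= H || tj[t] < 0 || tj[t] >= W) v = fill;
            else v = src(ti[t], tj[t], c);
            acc += wts[t] * v;
          }
          y(oi, oj, c) = acc;
        }
      }
    }
  }
  return y;
}

// Directed Hausdorff term: max over points of A of the distance to the
// nearest point of B. Points are 0-based (row, col) pixel coordinates.
// [[Rcpp::export]]
double cpp_directed_hausdorff(const arma::mat& A, const arma::mat& B) {
  double worst = 0.0;
  for (arma::uword a = 0; a < A.n_rows; ++a) {
    double best = std::numeric_limits<double>::infinity();
    const double ay = A(a, 0), ax = A(a, 1);
    for (arma::uword b = 0; b < B.n_rows; ++b) {
      const double dy = ay - B(b, 0), dx = ax - B(b, 1);
      const double d2 = dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}
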