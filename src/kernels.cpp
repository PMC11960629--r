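// Numerical kernels: the compact CNN (forward, backprop) and small image
// primitives (3x3 median, separable Gaussian blur, bilinear rotation).
//
// Layout conventions (must stay consistent with the R side):
//  - an activation map with C channels over an H x W grid is a C x (H*W)
//    matrix; pixel (i, j) (0-based) lives in column j*H + i;
//  - conv weights are (9*Cin) x Cout, row c*9 + (dj+1)*3 + (di+1) holds the
//    kernel tap at offset (di, dj) for input channel c ("same" zero padding);
//  - the flatten step is arma::vectorise of the C x (H*W) matrix, so the
//    channel index varies fastest.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col for a 3x3 "same" convolution; M is C x (H*W).
static mat im2col3(const mat& M, uword H, uword W) {
  const uword C = M.n_rows;
  mat out(9 * C, H * W, fill::zeros);
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const uword o = (uword)((dj + 1) * 3 + (di + 1));
      for (uword j = 0; j < W; ++j) {
        const int js = (int)j + dj;
        if (js < 0 || js >= (int)W) continue;
        const uword i0 = (di < 0) ? 1u : 0u;
        const uword i1 = (di > 0) ? H - 1 : H;
        for (uword i = i0; i < i1; ++i) {
          const uword dst = j * H + i;
          const uword src = (uword)js * H + (uword)((int)i + di);
          for (uword c = 0; c < C; ++c) out(c * 9 + o, dst) = M(c, src);
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter-add column gradients back onto the input grid
static mat col2im3(const mat& cols, uword H, uword W, uword C) {
  mat M(C, H * W, fill::zeros);
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      const uword o = (uword)((dj + 1) * 3 + (di + 1));
      for (uword j = 0; j < W; ++j) {
        const int js = (int)j + dj;
        if (js < 0 || js >= (int)W) continue;
        const uword i0 = (di < 0) ? 1u : 0u;
        const uword i1 = (di > 0) ? H - 1 : H;
        for (uword i = i0; i < i1; ++i) {
          const uword dst = j * H + i;
          const uword src = (uword)js * H + (uword)((int)i + di);
          for (uword c = 0; c < C; ++c) M(c, src) += cols(c * 9 + o, dst);
        }
      }
    }
  }
  return M;
}

// 2x2/stride-2 max pool with argmax bookkeeping; trailing odd row/col dropped
static mat pool2(const mat& M, uword H, uword W, umat& idx) {
  const uword C = M.n_rows, H2 = H / 2, W2 = W / 2;
  mat P(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (uword j = 0; j < W2; ++j) {
    for (uword i = 0; i < H2; ++i) {
      const uword dst = j * H2 + i;
      const uword s00 = (2 * j) * H + 2 * i;
      const uword s10 = s00 + 1, s01 = s00 + H, s11 = s01 + 1;
      for (uword c = 0; c < C; ++c) {
        double v = M(c, s00); uword b = s00;
        if (M(c, s10) > v) { v = M(c, s10); b = s10; }
        if (M(c, s01) > v) { v = M(c, s01); b = s01; }
        if (M(c, s11) > v) { v = M(c, s11); b = s11; }
        P(c, dst) = v; idx(c, dst) = b;
      }
    }
  }
  return P;
}

static mat unpool2(const mat& dP, const umat& idx, uword H, uword W) {
  mat dM(dP.n_rows, H * W, fill::zeros);
  for (uword k = 0; k < dP.n_cols; ++k)
    for (uword c = 0; c < dP.n_rows; ++c)
      dM(c, idx(c, k)) += dP(c, k);
  return dM;
}

static inline void relu_(mat& Z) { Z.transform([](double v) { return v > 0.0 ? v : 0.0; }); }

struct Acts {
  mat C1, Z1, P1, C2, Z2, P2, C3, Z3, P3, fd, z4, a1, a1d;
  umat i1, i2, i3;
  vec mask_conv, mask_fc;
  vec p; // softmax output
};

// forward pass for one image (M0: 1 x H*W); dropout masks are inverted
// (divide-by-keep) and all-ones at inference
static void fwd_one(const mat& M0, uword H, uword W,
                    const mat& W1, const vec& b1, const mat& W2, const vec& b2,
                    const mat& W3, const vec& b3, const mat& W4, const vec& b4,
                    const mat& W5, const vec& b5,
                    double p_conv, double p_fc, bool training, Acts& A) {
  const uword H1 = H / 2, Wd1 = W / 2;
  const uword H2 = H1 / 2, Wd2 = Wd1 / 2;
  const uword H3 = H2 / 2, Wd3 = Wd2 / 2;

  A.C1 = im2col3(M0, H, W);
  A.Z1 = W1.t() * A.C1; A.Z1.each_col() += b1;
  mat R1 = A.Z1; relu_(R1);
  A.P1 = pool2(R1, H, W, A.i1);

  A.C2 = im2col3(A.P1, H1, Wd1);
  A.Z2 = W2.t() * A.C2; A.Z2.each_col() += b2;
  mat R2 = A.Z2; relu_(R2);
  A.P2 = pool2(R2, H1, Wd1, A.i2);

  A.C3 = im2col3(A.P2, H2, Wd2);
  A.Z3 = W3.t() * A.C3; A.Z3.each_col() += b3;
  mat R3 = A.Z3; relu_(R3);
  A.P3 = pool2(R3, H2, Wd2, A.i3);

  vec f = vectorise(A.P3);
  if (training && p_conv > 0.0) {
    A.mask_conv.set_size(f.n_elem);
    for (uword k = 0; k < f.n_elem; ++k)
      A.mask_conv(k) = (unif_rand() >= p_conv) ? 1.0 / (1.0 - p_conv) : 0.0;
    A.fd = f % A.mask_conv;
  } else {
    A.mask_conv.reset();
    A.fd = f;
  }

  A.z4 = W4.t() * A.fd + b4;
  A.a1 = A.z4; relu_(A.a1);
  if (training && p_fc > 0.0) {
    A.mask_fc.set_size(A.a1.n_elem);
    for (uword k = 0; k < A.a1.n_elem; ++k)
      A.mask_fc(k) = (unif_rand() >= p_fc) ? 1.0 / (1.0 - p_fc) : 0.0;
    A.a1d = A.a1 % A.mask_fc;
  } else {
    A.mask_fc.reset();
    A.a1d = A.a1;
  }

  vec z = W5.t() * A.a1d + b5;
  z -= z.max();
  vec e = exp(z);
  A.p = e / accu(e);
  (void)H3; (void)Wd3;
}

// [[Rcpp::export]]
arma::mat cnn_forward_batch(const arma::cube& X, const Rcpp::List& w) {
  const uword H = X.n_rows, W = X.n_cols, N = X.n_slices;
  const mat W1 = w["W1"], W2 = w["W2"], W3 = w["W3"], W4 = w["W4"], W5 = w["W5"];
  const vec b1 = w["b1"], b2 = w["b2"], b3 = w["b3"], b4 = w["b4"], b5 = w["b5"];
  mat out(N, 2);
  Acts A;
  for (uword n = 0; n < N; ++n) {
    mat M0 = reshape(X.slice(n), 1, H * W);
    fwd_one(M0, H, W, W1, b1, W2, b2, W3, b3, W4, b4, W5, b5, 0.0, 0.0, false, A);
    out(n, 0) = A.p(0); out(n, 1) = A.p(1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_grad_batch(const arma::cube& X, const arma::ivec& y,
                          const Rcpp::List& w, double p_conv, double p_fc) {
  const uword H = X.n_rows, W = X.n_cols, N = X.n_slices;
  const mat W1 = w["W1"], W2 = w["W2"], W3 = w["W3"], W4 = w["W4"], W5 = w["W5"];
  const vec b1 = w["b1"], b2 = w["b2"], b3 = w["b3"], b4 = w["b4"], b5 = w["b5"];
  const uword H1 = H / 2, Wd1 = W / 2, H2 = H1 / 2, Wd2 = Wd1 / 2;

  mat gW1(size(W1), fill::zeros), gW2(size(W2), fill::zeros),
      gW3(size(W3), fill::zeros), gW4(size(W4), fill::zeros),
      gW5(size(W5), fill::zeros);
  vec gb1(size(b1), fill::zeros), gb2(size(b2), fill::zeros),
      gb3(size(b3), fill::zeros), gb4(size(b4), fill::zeros),
      gb5(size(b5), fill::zeros);

  double loss = 0.0; uword correct = 0;
  Acts A;
  for (uword n = 0; n < N; ++n) {
    mat M0 = reshape(X.slice(n), 1, H * W);
    fwd_one(M0, H, W, W1, b1, W2, b2, W3, b3, W4, b4, W5, b5,
            p_conv, p_fc, true, A);
    const int yi = y(n);
    loss += -std::log(std::max(A.p(yi), 1e-12));
    if ((A.p(1) > A.p(0) ? 1 : 0) == yi) ++correct;

    vec dz = A.p; dz(yi) -= 1.0;
    gW5 += A.a1d * dz.t(); gb5 += dz;
    vec da1 = W5 * dz;
    if (A.mask_fc.n_elem) da1 %= A.mask_fc;
    for (uword k = 0; k < da1.n_elem; ++k) if (A.z4(k) <= 0.0) da1(k) = 0.0;
    gW4 += A.fd * da1.t(); gb4 += da1;
    vec df = W4 * da1;
    if (A.mask_conv.n_elem) df %= A.mask_conv;

    mat dP3 = reshape(df, A.P3.n_rows, A.P3.n_cols);
    mat dR3 = unpool2(dP3, A.i3, H2, Wd2);
    for (uword k = 0; k < dR3.n_elem; ++k) if (A.Z3(k) <= 0.0) dR3(k) = 0.0;
    gW3 += A.C3 * dR3.t(); gb3 += sum(dR3, 1);
    mat dP2 = col2im3(W3 * dR3, H2, Wd2, 64);

    mat dR2 = unpool2(dP2, A.i2, H1, Wd1);
    for (uword k = 0; k < dR2.n_elem; ++k) if (A.Z2(k) <= 0.0) dR2(k) = 0.0;
    gW2 += A.C2 * dR2.t(); gb2 += sum(dR2, 1);
    mat dP1 = col2im3(W2 * dR2, H1, Wd1, 32);

    mat dR1 = unpool2(dP1, A.i1, H, W);
    for (uword k = 0; k < dR1.n_elem; ++k) if (A.Z1(k) <= 0.0) dR1(k) = 0.0;
    gW1 += A.C1 * dR1.t(); gb1 += sum(dR1, 1);
  }

  const double inv = 1.0 / (double)N;
  return List::create(
    _["loss"] = loss * inv,
    _["acc"] = (double)correct * inv,
    _["grads"] = List::create(
      _["W1"] = gW1 * inv, _["b1"] = gb1 * inv,
      _["W2"] = gW2 * inv, _["b2"] = gb2 * inv,
      _["W3"] = gW3 * inv, _["b3"] = gb3 * inv,
      _["W4"] = gW4 * inv, _["b4"] = gb4 * inv,
      _["W5"] = gW5 * inv, _["b5"] = gb5 * inv));
}

// 3x3 median filter, edge-replicated
// [[Rcpp::export]]
arma::mat median3_filter(const arma::mat& img) {
  const sword H = img.n_rows, W = img.n_cols;
  mat out(H, W);
  double v[9];
  for (sword j = 0; j < W; ++j) {
    for (sword i = 0; i < H; ++i) {
      int k = 0;
      for (sword dj = -1; dj <= 1; ++dj)
        for (sword di = -1; di <= 1; ++di) {
          sword ii = std::min(std::max(i + di, (sword)0), H - 1);
          sword jj = std::min(std::max(j + dj, (sword)0), W - 1);
          v[k++] = img(ii, jj);
        }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}

// separable Gaussian blur, edge-replicated; kernel radius 3*sigma
// [[Rcpp::export]]
arma::mat gauss_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  for (int t = -r; t <= r; ++t) k(t + r) = std::exp(-0.5 * t * t / (sigma * sigma));
  k /= accu(k);
  const sword H = img.n_rows, W = img.n_cols;
  mat tmp(H, W), out(H, W);
  for (sword j = 0; j < W; ++j)
    for (sword i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        sword ii = std::min(std::max(i + t, (sword)0), H - 1);
        s += k(t + r) * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (sword j = 0; j < W; ++j)
    for (sword i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        sword jj = std::min(std::max(j + t, (sword)0), W - 1);
        s += k(t + r) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// rotate about the image centre by `deg` degrees, bilinear, zero fill
// [[Rcpp::export]]
arma::mat rotate_bilinear(const arma::mat& img, double deg) {
  const sword H = img.n_rows, W = img.n_cols;
  const double th = deg * M_PI / 180.0, c = std::cos(th), s = std::sin(th);
  const double ci = (H - 1) / 2.0, cj = (W - 1) / 2.0;
  mat out(H, W, fill::zeros);
  for (sword j = 0; j < W; ++j) {
    for (sword i = 0; i < H; ++i) {
      const double di = i - ci, dj = j - cj;
      const double si = c * di - s * dj + ci;  // inverse rotation
      const double sj = s * di + c * dj + cj;
      const sword i0 = (sword)std::floor(si), j0 = (sword)std::floor(sj);
      if (i0 < 0 || j0 < 0 || i0 >= H - 1 || j0 >= W - 1) {
        if (si >= -0.5 && sj >= -0.5 && si <= H - 0.5 && sj <= W - 0.5) {
          sword ii = std::min(std::max((sword)std::round(si), (sword)0), H - 1);
          sword jj = std::min(std::max((sword)std::round(sj), (sword)0), W - 1);
          out(i, j) = img(ii, jj);
        }
        continue;
      }
      const double fi = si - i0, fj = sj - j0;
      out(i, j) = (1 - fi) * (1 - fj) * img(i0, j0) + fi * (1 - fj) * img(i0 + 1, j0)
                + (1 - fi) * fj * img(i0, j0 + 1) + fi * fj * img(i0 + 1, j0 + 1);
    }
  }
  return out;
}
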