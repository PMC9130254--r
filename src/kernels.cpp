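// Numerical kernels: im2col GEMM convolutions (forward/backward), 2x2
// transposed convolution, max-pooling, nearest-neighbour up/down sampling,
// bilinear/nearest warping, exact 3-D Euclidean distance transform and
// inscribed-sphere stamping, separable Gaussian blur.
//
// Feature maps are arma::cube (rows x cols x channels); conv weights are
// matrices of shape (kh*kw*Cin) x Cout with row index ki + kj*kh + c*kh*kw.
// "Same" padding follows the ceil(H/stride) output-size convention with the
// extra padding pixel on the high side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int& Ho, int& Wo, int& ph0, int& pw0) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  Ho = (H + stride - 1) / stride;
  Wo = (Wd + stride - 1) / stride;
  const int pad_h = std::max((Ho - 1) * stride + kh - H, 0);
  const int pad_w = std::max((Wo - 1) * stride + kw - Wd, 0);
  ph0 = pad_h / 2;
  pw0 = pad_w / 2;
  arma::mat M((size_t)Ho * Wo, (size_t)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = ki + kj * (size_t)kh + c * (size_t)kh * kw;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride + kj - pw0;
          if (sj < 0 || sj >= Wd) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride + ki - ph0;
            if (si < 0 || si >= H) continue;
            M(i + (size_t)j * Ho, col) = x(si, sj, c);
          }
        }
      }
  return M;
}

// [[Rcpp::export]]
arma::cube cs_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int kh, int kw, int stride) {
  const int Cout = W.n_cols;
  if (kh == 1 && kw == 1 && stride == 1) {
    const size_t n = (size_t)x.n_rows * x.n_cols;
    arma::mat X(const_cast<double*>(x.memptr()), n, x.n_slices, false, true);
    arma::mat out = X * W;
    out.each_row() += b.t();
    arma::cube o(x.n_rows, x.n_cols, Cout);
    std::memcpy(o.memptr(), out.memptr(), sizeof(double) * out.n_elem);
    return o;
  }
  int Ho, Wo, ph0, pw0;
  arma::mat M = im2col(x, kh, kw, stride, Ho, Wo, ph0, pw0);
  arma::mat out = M * W;
  out.each_row() += b.t();
  arma::cube o(Ho, Wo, Cout);
  std::memcpy(o.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return o;
}

// [[Rcpp::export]]
List cs_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                   const arma::cube& gout, int kh, int kw, int stride) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = W.n_cols;
  const size_t npix = (size_t)gout.n_rows * gout.n_cols;
  arma::mat G(const_cast<double*>(gout.memptr()), npix, Cout, false, true);
  arma::vec gb = arma::sum(G, 0).t();

  if (kh == 1 && kw == 1 && stride == 1) {
    arma::mat X(const_cast<double*>(x.memptr()), npix, C, false, true);
    arma::mat gW = X.t() * G;
    arma::mat gX = G * W.t();
    arma::cube gx(H, Wd, C);
    std::memcpy(gx.memptr(), gX.memptr(), sizeof(double) * gX.n_elem);
    return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
  }

  int Ho, Wo, ph0, pw0;
  arma::mat M = im2col(x, kh, kw, stride, Ho, Wo, ph0, pw0);
  arma::mat gW = M.t() * G;
  arma::mat gM = G * W.t();
  arma::cube gx(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = ki + kj * (size_t)kh + c * (size_t)kh * kw;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride + kj - pw0;
          if (sj < 0 || sj >= Wd) continue;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * stride + ki - ph0;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gM(i + (size_t)j * Ho, col);
          }
        }
      }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2, stride 2 (exact x2 upsampling).
// Weight layout: (Cin) x (4*Cout), column q = (di + 2*dj) + 4*cout.
// [[Rcpp::export]]
arma::cube cs_tconv2_fwd(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = W.n_cols / 4;
  const size_t n = (size_t)H * Wd;
  arma::mat X(const_cast<double*>(x.memptr()), n, C, false, true);
  arma::mat P = X * W;  // n x 4Cout
  arma::cube o(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const size_t q = di + 2 * (size_t)dj + 4 * (size_t)co;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            o(2 * i + di, 2 * j + dj, co) = P(i + (size_t)j * H, q) + b[co];
      }
  return o;
}

// [[Rcpp::export]]
List cs_tconv2_bwd(const arma::cube& x, const arma::mat& W,
                   const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = W.n_cols / 4;
  const size_t n = (size_t)H * Wd;
  arma::mat gP(n, 4 * (size_t)Cout);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const size_t q = di + 2 * (size_t)dj + 4 * (size_t)co;
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i) {
            const double g = gout(2 * i + di, 2 * j + dj, co);
            gP(i + (size_t)j * H, q) = g;
            s += g;
          }
      }
    gb[co] = s;
  }
  arma::mat X(const_cast<double*>(x.memptr()), n, C, false, true);
  arma::mat gW = X.t() * gP;
  arma::mat gX = gP * W.t();
  arma::cube gx(H, Wd, C);
  std::memcpy(gx.memptr(), gX.memptr(), sizeof(double) * gX.n_elem);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List cs_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows / 2, Wd = x.n_cols / 2, C = x.n_slices;
  arma::cube o(H, Wd, C);
  IntegerVector idx((size_t)H * Wd * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wd; ++j)
      for (int i = 0; i < H; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; arg = di + 2 * dj; }
          }
        o(i, j, c) = best;
        idx[p++] = arg;
      }
  // column-major order of idx matches (i, j, c) traversal? traversal above is
  // c outer, j, i inner -> index i + j*H + c*H*Wd only if p advances in that
  // order; it does (i fastest).
  return List::create(_["out"] = o, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cs_maxpool2_bwd(const arma::cube& gout, const IntegerVector& idx) {
  const int H = gout.n_rows, Wd = gout.n_cols, C = gout.n_slices;
  arma::cube gx(2 * H, 2 * Wd, C, arma::fill::zeros);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wd; ++j)
      for (int i = 0; i < H; ++i) {
        const int a = idx[p++];
        gx(2 * i + (a & 1), 2 * j + (a >> 1), c) += gout(i, j, c);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cs_upnn_fwd(const arma::cube& x, int f) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  arma::cube o(H * f, Wd * f, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wd * f; ++j)
      for (int i = 0; i < H * f; ++i)
        o(i, j, c) = x(i / f, j / f, c);
  return o;
}

// [[Rcpp::export]]
arma::cube cs_upnn_bwd(const arma::cube& gout, int f) {
  const int H = gout.n_rows / f, Wd = gout.n_cols / f, C = gout.n_slices;
  arma::cube gx(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < (int)gout.n_cols; ++j)
      for (int i = 0; i < (int)gout.n_rows; ++i)
        gx(i / f, j / f, c) += gout(i, j, c);
  return gx;
}

// Geometric warp: out(i,j) = img sampled at 0-based source coords
// (mr(i,j), mc(i,j)); bilinear or nearest; outside the image -> fill.
// [[Rcpp::export]]
arma::mat cs_warp(const arma::mat& img, const arma::mat& mr,
                  const arma::mat& mc, bool bilinear, double fill) {
  const int Ho = mr.n_rows, Wo = mr.n_cols;
  const int H = img.n_rows, Wd = img.n_cols;
  arma::mat out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      const double r = mr(i, j), c = mc(i, j);
      if (bilinear) {
        if (r <= -1.0 || c <= -1.0 || r >= H || c >= Wd) { out(i, j) = fill; continue; }
        const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
        const double fr = r - r0, fc = c - c0;
        double v = 0.0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ri = r0 + di, ci = c0 + dj;
            const double w = (di ? fr : 1.0 - fr) * (dj ? fc : 1.0 - fc);
            if (w == 0.0) continue;
            const double px = (ri >= 0 && ri < H && ci >= 0 && ci < Wd)
                                ? img(ri, ci) : fill;
            v += w * px;
          }
        out(i, j) = v;
      } else {
        const int ri = (int)std::lround(r), ci = (int)std::lround(c);
        out(i, j) = (ri >= 0 && ri < H && ci >= 0 && ci < Wd) ? img(ri, ci) : fill;
      }
    }
  return out;
}

// ---- Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// 3-D, distance of every voxel to the nearest background (FALSE) voxel center.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -arma::datum::inf;
  z[1] = arma::datum::inf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = arma::datum::inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cs_edt_sq(const LogicalVector& fg, const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t N = (size_t)n1 * n2 * n3;
  const double INF = 1e18;
  std::vector<double> d(N);
  for (size_t i = 0; i < N; ++i) d[i] = fg[i] ? INF : 0.0;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (fastest index)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const size_t base = (size_t)j * n1 + (size_t)k * n1 * n2;
      for (int i = 0; i < n1; ++i) f[i] = d[base + i];
      dt1d(f, dd, v, z, n1);
      for (int i = 0; i < n1; ++i) d[base + i] = dd[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)i + (size_t)k * n1 * n2;
      for (int j = 0; j < n2; ++j) f[j] = d[base + (size_t)j * n1];
      dt1d(f, dd, v, z, n2);
      for (int j = 0; j < n2; ++j) d[base + (size_t)j * n1] = dd[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)i + (size_t)j * n1;
      for (int k = 0; k < n3; ++k) f[k] = d[base + (size_t)k * n1 * n2];
      dt1d(f, dd, v, z, n3);
      for (int k = 0; k < n3; ++k) d[base + (size_t)k * n1 * n2] = dd[k];
    }
  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = d[i];
  return out;
}

// Inscribed-sphere stamping: r holds, per foreground voxel, the
// center-to-background distance dt(c) (0 elsewhere). For every voxel v the
// result is max{ dt(c) : ||v - c|| < dt(c) }, computed by visiting centers in
// decreasing dt order and stamping strictly-interior voxels.
// [[Rcpp::export]]
NumericVector cs_thickness_stamp(const NumericVector& r,
                                 const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t N = (size_t)n1 * n2 * n3;
  std::vector<size_t> ord;
  ord.reserve(N / 8);
  for (size_t i = 0; i < N; ++i)
    if (r[i] > 0) ord.push_back(i);
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return r[a] > r[b]; });
  NumericVector th(N, 0.0);
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    const size_t c = ord[oi];
    const double rc = r[c];
    const int ci = c % n1;
    const int cj = (c / n1) % n2;
    const int ck = c / ((size_t)n1 * n2);
    const double r2 = rc * rc - 1e-9;
    const int R = (int)std::floor(std::sqrt(std::max(r2, 0.0)));
    for (int dk = -R; dk <= R; ++dk) {
      const int k = ck + dk;
      if (k < 0 || k >= n3) continue;
      for (int dj = -R; dj <= R; ++dj) {
        const int j = cj + dj;
        if (j < 0 || j >= n2) continue;
        const double d2 = (double)dk * dk + (double)dj * dj;
        if (d2 >= r2) continue;
        const int di_max = (int)std::floor(std::sqrt(r2 - d2));
        const size_t base = (size_t)j * n1 + (size_t)k * n1 * n2;
        for (int di = -di_max; di <= di_max; ++di) {
          const int i = ci + di;
          if (i < 0 || i >= n1) continue;
          if (th[base + i] < rc) th[base + i] = rc;
        }
      }
    }
  }
  return th;
}

// Separable 3-D Gaussian blur, reflecting boundaries, truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cs_blur3d(const NumericVector& x, const IntegerVector& dims,
                        double sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t N = (size_t)n1 * n2 * n3;
  if (sigma <= 0) return clone(x);
  const int R = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * R + 1);
  double s = 0;
  for (int t = -R; t <= R; ++t) {
    ker[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + R];
  }
  for (auto& v : ker) v /= s;
  std::vector<double> a(x.begin(), x.end()), b(N);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const size_t base = (size_t)j * n1 + (size_t)k * n1 * n2;
      for (int i = 0; i < n1; ++i) {
        double v = 0;
        for (int t = -R; t <= R; ++t) v += ker[t + R] * a[base + reflect(i + t, n1)];
        b[base + i] = v;
      }
    }
  a.swap(b);
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)i + (size_t)k * n1 * n2;
      for (int j = 0; j < n2; ++j) {
        double v = 0;
        for (int t = -R; t <= R; ++t)
          v += ker[t + R] * a[base + (size_t)reflect(j + t, n2) * n1];
        b[base + (size_t)j * n1] = v;
      }
    }
  a.swap(b);
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)i + (size_t)j * n1;
      for (int k = 0; k < n3; ++k) {
        double v = 0;
        for (int t = -R; t <= R; ++t)
          v += ker[t + R] * a[base + (size_t)reflect(k + t, n3) * n1 * n2];
        b[base + (size_t)k * n1 * n2] = v;
      }
    }
  NumericVector out(N);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}
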