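#include <Rcpp.h>
using namespace Rcpp;

// Array layout: column-major R arrays.
// Volumes: [X, Y, Z]; feature tensors: [X, Y, Z, C]; kernels: [k1, k2, k3, Cin, Cout];
// displacement fields: [X, Y, Z, 3] in voxel units, component order (dx, dy, dz).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// 3D convolution, zero-padded "same", odd kernel sizes
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector b) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], Co = wd[4];
  const int r1 = k1 / 2, r2 = k2 / 2, r3 = k3 / 2;
  NumericVector y(static_cast<R_xlen_t>(X) * Y * Z * Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  const R_xlen_t xsl = static_cast<R_xlen_t>(X) * Y * Z;
  for (int co = 0; co < Co; ++co) {
    const double bias = b[co];
    for (int k = 0; k < Z; ++k)
      for (int j = 0; j < Y; ++j)
        for (int i = 0; i < X; ++i) {
          double acc = bias;
          for (int ci = 0; ci < Ci; ++ci) {
            const double* xc = px + ci * xsl;
            const double* wc = pw + (static_cast<R_xlen_t>(k1) * k2 * k3) * (ci + static_cast<R_xlen_t>(Ci) * co);
            for (int c3 = 0; c3 < k3; ++c3) {
              int kk = k + c3 - r3; if (kk < 0 || kk >= Z) continue;
              for (int c2 = 0; c2 < k2; ++c2) {
                int jj = j + c2 - r2; if (jj < 0 || jj >= Y) continue;
                for (int c1 = 0; c1 < k1; ++c1) {
                  int ii = i + c1 - r1; if (ii < 0 || ii >= X) continue;
                  acc += xc[ii + static_cast<R_xlen_t>(X) * (jj + static_cast<R_xlen_t>(Y) * kk)] *
                         wc[c1 + k1 * (c2 + k2 * c3)];
                }
              }
            }
          }
          py[i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * (k + static_cast<R_xlen_t>(Z) * co))] = acc;
        }
  }
  return y;
}

// Backward pass: returns gx, gw, gb given upstream gradient gy.
// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector gy) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], Co = wd[4];
  const int r1 = k1 / 2, r2 = k2 / 2, r3 = k3 / 2;
  NumericVector gx(static_cast<R_xlen_t>(X) * Y * Z * Ci);
  NumericVector gw(w.size());
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  const R_xlen_t sl = static_cast<R_xlen_t>(X) * Y * Z;
  for (int co = 0; co < Co; ++co) {
    const double* gyc = pg + co * sl;
    double bacc = 0.0;
    for (R_xlen_t t = 0; t < sl; ++t) bacc += gyc[t];
    gb[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = px + ci * sl;
      double* gxc = pgx + ci * sl;
      const R_xlen_t woff = (static_cast<R_xlen_t>(k1) * k2 * k3) * (ci + static_cast<R_xlen_t>(Ci) * co);
      const double* wc = pw + woff;
      double* gwc = pgw + woff;
      for (int k = 0; k < Z; ++k)
        for (int j = 0; j < Y; ++j)
          for (int i = 0; i < X; ++i) {
            const double g = gyc[i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * k)];
            if (g == 0.0) continue;
            for (int c3 = 0; c3 < k3; ++c3) {
              int kk = k + c3 - r3; if (kk < 0 || kk >= Z) continue;
              for (int c2 = 0; c2 < k2; ++c2) {
                int jj = j + c2 - r2; if (jj < 0 || jj >= Y) continue;
                for (int c1 = 0; c1 < k1; ++c1) {
                  int ii = i + c1 - r1; if (ii < 0 || ii >= X) continue;
                  const R_xlen_t xi = ii + static_cast<R_xlen_t>(X) * (jj + static_cast<R_xlen_t>(Y) * kk);
                  const int wi = c1 + k1 * (c2 + k2 * c3);
                  gxc[xi] += g * wc[wi];
                  gwc[wi] += g * xc[xi];
                }
              }
            }
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Average pooling / nearest-neighbour upsampling (per-axis integer factors)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_avgpool_fwd")]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector xd, IntegerVector p) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int px_ = p[0], py_ = p[1], pz_ = p[2];
  const int Xo = X / px_, Yo = Y / py_, Zo = Z / pz_;
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * Zo * C);
  const double inv = 1.0 / (px_ * py_ * pz_);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          double acc = 0.0;
          for (int ck = 0; ck < pz_; ++ck)
            for (int cj = 0; cj < py_; ++cj)
              for (int ci = 0; ci < px_; ++ci)
                acc += x[(i * px_ + ci) + static_cast<R_xlen_t>(X) * ((j * py_ + cj) + static_cast<R_xlen_t>(Y) * ((k * pz_ + ck) + static_cast<R_xlen_t>(Z) * c))];
          y[i + static_cast<R_xlen_t>(Xo) * (j + static_cast<R_xlen_t>(Yo) * (k + static_cast<R_xlen_t>(Zo) * c))] = acc * inv;
        }
  return y;
}

// [[Rcpp::export(name = ".cpp_avgpool_bwd")]]
NumericVector cpp_avgpool_bwd(NumericVector gy, IntegerVector xd, IntegerVector p) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int px_ = p[0], py_ = p[1], pz_ = p[2];
  const int Xo = X / px_, Yo = Y / py_, Zo = Z / pz_;
  NumericVector gx(static_cast<R_xlen_t>(X) * Y * Z * C);
  const double inv = 1.0 / (px_ * py_ * pz_);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          const double g = gy[i + static_cast<R_xlen_t>(Xo) * (j + static_cast<R_xlen_t>(Yo) * (k + static_cast<R_xlen_t>(Zo) * c))] * inv;
          for (int ck = 0; ck < pz_; ++ck)
            for (int cj = 0; cj < py_; ++cj)
              for (int ci = 0; ci < px_; ++ci)
                gx[(i * px_ + ci) + static_cast<R_xlen_t>(X) * ((j * py_ + cj) + static_cast<R_xlen_t>(Y) * ((k * pz_ + ck) + static_cast<R_xlen_t>(Z) * c))] = g;
        }
  return gx;
}

// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xd, IntegerVector p) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int px_ = p[0], py_ = p[1], pz_ = p[2];
  const int Xo = X * px_, Yo = Y * py_, Zo = Z * pz_;
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * Zo * C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i)
          y[i + static_cast<R_xlen_t>(Xo) * (j + static_cast<R_xlen_t>(Yo) * (k + static_cast<R_xlen_t>(Zo) * c))] =
            x[(i / px_) + static_cast<R_xlen_t>(X) * ((j / py_) + static_cast<R_xlen_t>(Y) * ((k / pz_) + static_cast<R_xlen_t>(Z) * c))];
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector gy, IntegerVector xd, IntegerVector p) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int px_ = p[0], py_ = p[1], pz_ = p[2];
  const int Xo = X * px_, Yo = Y * py_, Zo = Z * pz_;
  NumericVector gx(static_cast<R_xlen_t>(X) * Y * Z * C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i)
          gx[(i / px_) + static_cast<R_xlen_t>(X) * ((j / py_) + static_cast<R_xlen_t>(Y) * ((k / pz_) + static_cast<R_xlen_t>(Z) * c))] +=
            gy[i + static_cast<R_xlen_t>(Xo) * (j + static_cast<R_xlen_t>(Yo) * (k + static_cast<R_xlen_t>(Zo) * c))];
  return gx;
}

// ---------------------------------------------------------------------------
// Trilinear warping: out(p) = img(p + disp(p)), clamped (zero-flux) boundaries
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_warp_fwd")]]
NumericVector cpp_warp_fwd(NumericVector img, IntegerVector d, NumericVector disp) {
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t sl = static_cast<R_xlen_t>(X) * Y * Z;
  NumericVector out(sl);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const R_xlen_t v = i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * k);
        double xs = i + disp[v];
        double ys = j + disp[v + sl];
        double zs = k + disp[v + 2 * sl];
        if (xs < 0) xs = 0; if (xs > X - 1) xs = X - 1;
        if (ys < 0) ys = 0; if (ys > Y - 1) ys = Y - 1;
        if (zs < 0) zs = 0; if (zs > Z - 1) zs = Z - 1;
        const int i0 = clampi(static_cast<int>(std::floor(xs)), 0, X - 1);
        const int j0 = clampi(static_cast<int>(std::floor(ys)), 0, Y - 1);
        const int k0 = clampi(static_cast<int>(std::floor(zs)), 0, Z - 1);
        const int i1 = clampi(i0 + 1, 0, X - 1);
        const int j1 = clampi(j0 + 1, 0, Y - 1);
        const int k1 = clampi(k0 + 1, 0, Z - 1);
        const double fx = xs - i0, fy = ys - j0, fz = zs - k0;
        double acc = 0.0;
        for (int ck = 0; ck < 2; ++ck)
          for (int cj = 0; cj < 2; ++cj)
            for (int ci = 0; ci < 2; ++ci) {
              const double wgt = (ci ? fx : 1 - fx) * (cj ? fy : 1 - fy) * (ck ? fz : 1 - fz);
              if (wgt == 0.0) continue;
              acc += wgt * img[(ci ? i1 : i0) + static_cast<R_xlen_t>(X) * ((cj ? j1 : j0) + static_cast<R_xlen_t>(Y) * (ck ? k1 : k0))];
            }
        out[v] = acc;
      }
  return out;
}

// Adjoint of the warp (exact transpose of the interpolation matrix):
// scatters y back with the trilinear weights.
// [[Rcpp::export(name = ".cpp_warp_adj")]]
NumericVector cpp_warp_adj(NumericVector y, IntegerVector d, NumericVector disp) {
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t sl = static_cast<R_xlen_t>(X) * Y * Z;
  NumericVector out(sl);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const R_xlen_t v = i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * k);
        const double g = y[v];
        if (g == 0.0) continue;
        double xs = i + disp[v];
        double ys = j + disp[v + sl];
        double zs = k + disp[v + 2 * sl];
        if (xs < 0) xs = 0; if (xs > X - 1) xs = X - 1;
        if (ys < 0) ys = 0; if (ys > Y - 1) ys = Y - 1;
        if (zs < 0) zs = 0; if (zs > Z - 1) zs = Z - 1;
        const int i0 = clampi(static_cast<int>(std::floor(xs)), 0, X - 1);
        const int j0 = clampi(static_cast<int>(std::floor(ys)), 0, Y - 1);
        const int k0 = clampi(static_cast<int>(std::floor(zs)), 0, Z - 1);
        const int i1 = clampi(i0 + 1, 0, X - 1);
        const int j1 = clampi(j0 + 1, 0, Y - 1);
        const int k1 = clampi(k0 + 1, 0, Z - 1);
        const double fx = xs - i0, fy = ys - j0, fz = zs - k0;
        for (int ck = 0; ck < 2; ++ck)
          for (int cj = 0; cj < 2; ++cj)
            for (int ci = 0; ci < 2; ++ci) {
              const double wgt = (ci ? fx : 1 - fx) * (cj ? fy : 1 - fy) * (ck ? fz : 1 - fz);
              if (wgt == 0.0) continue;
              out[(ci ? i1 : i0) + static_cast<R_xlen_t>(X) * ((cj ? j1 : j0) + static_cast<R_xlen_t>(Y) * (ck ? k1 : k0))] += g * wgt;
            }
      }
  return out;
}

// Gradient of warp output w.r.t. the displacement field (for motion-network
// training). Returns gdisp [X,Y,Z,3]: gout(p) times the spatial derivative of
// the trilinear interpolant at p + disp(p). Zero where sampling is clamped.
// [[Rcpp::export(name = ".cpp_warp_bwd_disp")]]
NumericVector cpp_warp_bwd_disp(NumericVector img, IntegerVector d,
                                NumericVector disp, NumericVector gout) {
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t sl = static_cast<R_xlen_t>(X) * Y * Z;
  NumericVector gdisp(3 * sl);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const R_xlen_t v = i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * k);
        const double g = gout[v];
        if (g == 0.0) continue;
        double xs = i + disp[v];
        double ys = j + disp[v + sl];
        double zs = k + disp[v + 2 * sl];
        const bool cx = (xs < 0 || xs > X - 1);
        const bool cy = (ys < 0 || ys > Y - 1);
        const bool cz = (zs < 0 || zs > Z - 1);
        if (xs < 0) xs = 0; if (xs > X - 1) xs = X - 1;
        if (ys < 0) ys = 0; if (ys > Y - 1) ys = Y - 1;
        if (zs < 0) zs = 0; if (zs > Z - 1) zs = Z - 1;
        const int i0 = clampi(static_cast<int>(std::floor(xs)), 0, X - 1);
        const int j0 = clampi(static_cast<int>(std::floor(ys)), 0, Y - 1);
        const int k0 = clampi(static_cast<int>(std::floor(zs)), 0, Z - 1);
        const int i1 = clampi(i0 + 1, 0, X - 1);
        const int j1 = clampi(j0 + 1, 0, Y - 1);
        const int k1 = clampi(k0 + 1, 0, Z - 1);
        const double fx = xs - i0, fy = ys - j0, fz = zs - k0;
        double gx = 0.0, gy = 0.0, gz = 0.0;
        for (int ck = 0; ck < 2; ++ck)
          for (int cj = 0; cj < 2; ++cj)
            for (int ci = 0; ci < 2; ++ci) {
              const double val = img[(ci ? i1 : i0) + static_cast<R_xlen_t>(X) * ((cj ? j1 : j0) + static_cast<R_xlen_t>(Y) * (ck ? k1 : k0))];
              const double wx = ci ? 1.0 : -1.0;
              const double wy = cj ? 1.0 : -1.0;
              const double wz = ck ? 1.0 : -1.0;
              gx += val * wx * (cj ? fy : 1 - fy) * (ck ? fz : 1 - fz);
              gy += val * (ci ? fx : 1 - fx) * wy * (ck ? fz : 1 - fz);
              gz += val * (ci ? fx : 1 - fx) * (cj ? fy : 1 - fy) * wz;
            }
        gdisp[v]          = cx ? 0.0 : g * gx;
        gdisp[v + sl]     = cy ? 0.0 : g * gy;
        gdisp[v + 2 * sl] = cz ? 0.0 : g * gz;
      }
  return gdisp;
}

// ---------------------------------------------------------------------------
// Box filter (uniform window mean) over the first three dims, clamped edges.
// Used by the SSIM implementation.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_boxfilter3")]]
NumericVector cpp_boxfilter3(NumericVector x, IntegerVector d, int radius) {
  const int X = d[0], Y = d[1], Z = d[2];
  NumericVector out(x.size());
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        double acc = 0.0;
        int n = 0;
        for (int ck = std::max(0, k - radius); ck <= std::min(Z - 1, k + radius); ++ck)
          for (int cj = std::max(0, j - radius); cj <= std::min(Y - 1, j + radius); ++cj)
            for (int ci = std::max(0, i - radius); ci <= std::min(X - 1, i + radius); ++ci) {
              acc += x[ci + static_cast<R_xlen_t>(X) * (cj + static_cast<R_xlen_t>(Y) * ck)];
              ++n;
            }
        out[i + static_cast<R_xlen_t>(X) * (j + static_cast<R_xlen_t>(Y) * k)] = acc / n;
      }
  return out;
}

// Trilinear sampling of a volume at arbitrary (0-based) points [n,3], clamped.
// [[Rcpp::export(name = ".cpp_sample_points")]]
NumericVector cpp_sample_points(NumericVector img, IntegerVector d, NumericMatrix pts) {
  const int X = d[0], Y = d[1], Z = d[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double xs = pts(t, 0), ys = pts(t, 1), zs = pts(t, 2);
    if (xs < 0) xs = 0; if (xs > X - 1) xs = X - 1;
    if (ys < 0) ys = 0; if (ys > Y - 1) ys = Y - 1;
    if (zs < 0) zs = 0; if (zs > Z - 1) zs = Z - 1;
    const int i0 = clampi(static_cast<int>(std::floor(xs)), 0, X - 1);
    const int j0 = clampi(static_cast<int>(std::floor(ys)), 0, Y - 1);
    const int k0 = clampi(static_cast<int>(std::floor(zs)), 0, Z - 1);
    const int i1 = clampi(i0 + 1, 0, X - 1);
    const int j1 = clampi(j0 + 1, 0, Y - 1);
    const int k1 = clampi(k0 + 1, 0, Z - 1);
    const double fx = xs - i0, fy = ys - j0, fz = zs - k0;
    double acc = 0.0;
    for (int ck = 0; ck < 2; ++ck)
      for (int cj = 0; cj < 2; ++cj)
        for (int ci = 0; ci < 2; ++ci)
          acc += (ci ? fx : 1 - fx) * (cj ? fy : 1 - fy) * (ck ? fz : 1 - fz) *
                 img[(ci ? i1 : i0) + static_cast<R_xlen_t>(X) * ((cj ? j1 : j0) + static_cast<R_xlen_t>(Y) * (ck ? k1 : k0))];
    out[t] = acc;
  }
  return out;
}
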