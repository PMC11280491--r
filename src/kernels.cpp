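// Compute kernels for the segmentation network.
//
// Array conventions (matching the R side):
//   feature maps  : numeric array dim c(C, H, W), column-major, so element
//                   (c,h,w) sits at c + C*(h + H*w)  (all 0-based here)
//   conv weights  : dim c(O, C, kh, kw)
//   coordinates   : (row, col), 0-based, top-left origin
#include <Rcpp.h>
#include <zlib.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2];
  const int O = wd[0], kh = wd[2], kw = wd[3];
  if (wd[1] != C) stop("conv2d: weight expects %d input channels, got %d", (int)wd[1], C);
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector y((R_xlen_t)O * Ho * Wo);
  y.attr("dim") = Dimension(O, Ho, Wo);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *yo = py + (size_t)O * (ho + (size_t)Ho * wo);
      for (int o = 0; o < O; ++o) yo[o] = pb[o];
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wo * stride - pad + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          const double *xc = px + (size_t)C * (hi + (size_t)H * wi);
          const double *wk = pw + (size_t)O * C * (ki + (size_t)kh * kj);
          for (int c = 0; c < C; ++c) {
            const double xv = xc[c];
            if (xv == 0.0) continue;
            const double *woc = wk + (size_t)O * c;
            for (int o = 0; o < O; ++o) yo[o] += woc[o] * xv;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2];
  const int O = wd[0], kh = wd[2], kw = wd[3];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector dx((R_xlen_t)C * H * W), dw(w.size()), db(O);
  dx.attr("dim") = Dimension(C, H, W);
  dw.attr("dim") = IntegerVector::create(O, C, kh, kw);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *dyo = pdy + (size_t)O * (ho + (size_t)Ho * wo);
      for (int o = 0; o < O; ++o) pdb[o] += dyo[o];
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wo * stride - pad + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          const double *xc = px + (size_t)C * (hi + (size_t)H * wi);
          double *dxc = pdx + (size_t)C * (hi + (size_t)H * wi);
          const size_t wbase = (size_t)O * C * (ki + (size_t)kh * kj);
          for (int c = 0; c < C; ++c) {
            const double xv = xc[c];
            const double *woc = pw + wbase + (size_t)O * c;
            double *dwoc = pdw + wbase + (size_t)O * c;
            double acc = 0.0;
            for (int o = 0; o < O; ++o) {
              const double g = dyo[o];
              acc += woc[o] * g;
              dwoc[o] += g * xv;
            }
            dxc[c] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, kernel 2, stride 2 (exact x2 upsampling).
// weights dim c(C, O, 2, 2)
// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], O = wd[1];
  if (wd[0] != C) stop("convT2d: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)O * Ho * Wo);
  y.attr("dim") = Dimension(O, Ho, Wo);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) py[i] = pb[i % O];
  for (int wi = 0; wi < W; ++wi) {
    for (int hi = 0; hi < H; ++hi) {
      const double *xc = px + (size_t)C * (hi + (size_t)H * wi);
      for (int dj = 0; dj < 2; ++dj) {
        for (int di = 0; di < 2; ++di) {
          double *yo = py + (size_t)O * ((2 * hi + di) + (size_t)Ho * (2 * wi + dj));
          const double *wk = pw + (size_t)C * O * (di + 2 * (size_t)dj);
          for (int c = 0; c < C; ++c) {
            const double xv = xc[c];
            if (xv == 0.0) continue;
            const double *wco = wk + c; // stride C over o
            for (int o = 0; o < O; ++o) yo[o] += wco[(size_t)C * o] * xv;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], O = wd[1];
  const int Ho = 2 * H;
  NumericVector dx((R_xlen_t)C * H * W), dw(w.size()), db(O);
  dx.attr("dim") = Dimension(C, H, W);
  dw.attr("dim") = IntegerVector::create(C, O, 2, 2);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int wi = 0; wi < W; ++wi) {
    for (int hi = 0; hi < H; ++hi) {
      const double *xc = px + (size_t)C * (hi + (size_t)H * wi);
      double *dxc = pdx + (size_t)C * (hi + (size_t)H * wi);
      for (int dj = 0; dj < 2; ++dj) {
        for (int di = 0; di < 2; ++di) {
          const double *dyo = pdy + (size_t)O * ((2 * hi + di) + (size_t)Ho * (2 * wi + dj));
          const size_t wbase = (size_t)C * O * (di + 2 * (size_t)dj);
          if (di == 0 && dj == 0 && hi == 0 && wi == 0)
            ; // db handled below once per output pixel anyway
          for (int o = 0; o < O; ++o) {
            const double g = dyo[o];
            if (g == 0.0) continue;
            const double *wco = pw + wbase + (size_t)C * o;
            double *dwco = pdw + wbase + (size_t)C * o;
            for (int c = 0; c < C; ++c) {
              dxc[c] += wco[c] * g;
              dwco[c] += xc[c] * g;
            }
          }
        }
      }
    }
  }
  const int Wo = 2 * W;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double *dyo = pdy + (size_t)O * (ho + (size_t)Ho * wo);
      for (int o = 0; o < O; ++o) pdb[o] += dyo[o];
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// DCNv3 sampling core.
// x      : (C,H,W), C divisible by G
// off    : (2*G*K, H, W), channel = d + 2*(k + K*g), d=0 row offset, d=1 col
// m      : (G*K, H, W),  channel = k + K*g, already softmax-normalised over k
// pk     : (2, K) fixed base grid offsets (row, col)
// Output : (C,H,W); y[c] = sum_k m[g(c),k] * bilinear(x_c, p + pk + dp[g,k])
// (The per-group projection w_g is applied on the R side.)
static inline void bilin_weights(double r, double c, int H, int W,
                                 int *r0, int *c0, double *wts) {
  const double rf = std::floor(r), cf = std::floor(c);
  *r0 = (int)rf; *c0 = (int)cf;
  const double ar = r - rf, ac = c - cf;
  wts[0] = (1 - ar) * (1 - ac); // (r0, c0)
  wts[1] = ar * (1 - ac);       // (r0+1, c0)
  wts[2] = (1 - ar) * ac;       // (r0, c0+1)
  wts[3] = ar * ac;             // (r0+1, c0+1)
}

// [[Rcpp::export]]
NumericVector cpp_dcn_fwd(NumericVector x, NumericVector off, NumericVector m,
                          NumericMatrix pk, int G) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2];
  const int K = pk.ncol();
  const int Cg = C / G;
  NumericVector y((R_xlen_t)C * H * W);
  y.attr("dim") = Dimension(C, H, W);
  const double *px = x.begin(), *poff = off.begin(), *pm = m.begin();
  double *py = y.begin();
  const int OC = 2 * G * K, MC = G * K;
  for (int wq = 0; wq < W; ++wq) {
    for (int hq = 0; hq < H; ++hq) {
      const size_t pix = hq + (size_t)H * wq;
      const double *offp = poff + (size_t)OC * pix;
      const double *mp = pm + (size_t)MC * pix;
      double *yo = py + (size_t)C * pix;
      for (int g = 0; g < G; ++g) {
        for (int k = 0; k < K; ++k) {
          const double mw = mp[k + K * g];
          const double r = hq + pk(0, k) + offp[0 + 2 * (k + K * g)];
          const double c = wq + pk(1, k) + offp[1 + 2 * (k + K * g)];
          int r0, c0; double wt[4];
          bilin_weights(r, c, H, W, &r0, &c0, wt);
          for (int q = 0; q < 4; ++q) {
            const int rr = r0 + (q & 1), cc = c0 + (q >> 1);
            if (rr < 0 || rr >= H || cc < 0 || cc >= W || wt[q] == 0.0) continue;
            const double f = mw * wt[q];
            const double *xs = px + (size_t)C * (rr + (size_t)H * cc);
            for (int cg = 0; cg < Cg; ++cg) {
              const int ch = g * Cg + cg;
              yo[ch] += f * xs[ch];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dcn_bwd(NumericVector x, NumericVector off, NumericVector m,
                 NumericMatrix pk, int G, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2];
  const int K = pk.ncol();
  const int Cg = C / G;
  NumericVector dx((R_xlen_t)C * H * W), doff(off.size()), dm(m.size());
  dx.attr("dim") = Dimension(C, H, W);
  doff.attr("dim") = Dimension(2 * G * K, H, W);
  dm.attr("dim") = Dimension(G * K, H, W);
  const double *px = x.begin(), *poff = off.begin(), *pm = m.begin(),
               *pdy = dy.begin();
  double *pdx = dx.begin(), *pdoff = doff.begin(), *pdm = dm.begin();
  const int OC = 2 * G * K, MC = G * K;
  for (int wq = 0; wq < W; ++wq) {
    for (int hq = 0; hq < H; ++hq) {
      const size_t pix = hq + (size_t)H * wq;
      const double *offp = poff + (size_t)OC * pix;
      const double *mp = pm + (size_t)MC * pix;
      const double *dyo = pdy + (size_t)C * pix;
      double *doffp = pdoff + (size_t)OC * pix;
      double *dmp = pdm + (size_t)MC * pix;
      for (int g = 0; g < G; ++g) {
        for (int k = 0; k < K; ++k) {
          const double mw = mp[k + K * g];
          const double r = hq + pk(0, k) + offp[0 + 2 * (k + K * g)];
          const double c = wq + pk(1, k) + offp[1 + 2 * (k + K * g)];
          const double rf = std::floor(r), cf = std::floor(c);
          const int r0 = (int)rf, c0 = (int)cf;
          const double ar = r - rf, ac = c - cf;
          // corner validity and pointers
          double v[4] = {0, 0, 0, 0};
          double dval_sum = 0.0, dr_acc = 0.0, dc_acc = 0.0;
          for (int cg = 0; cg < Cg; ++cg) {
            const int ch = g * Cg + cg;
            const double g_out = dyo[ch];
            // gather corner values for this channel
            double vq[4] = {0, 0, 0, 0};
            for (int q = 0; q < 4; ++q) {
              const int rr = r0 + (q & 1), cc = c0 + (q >> 1);
              if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
              vq[q] = px[ch + (size_t)C * (rr + (size_t)H * cc)];
            }
            const double val = (1 - ar) * (1 - ac) * vq[0] + ar * (1 - ac) * vq[1] +
                               (1 - ar) * ac * vq[2] + ar * ac * vq[3];
            dval_sum += g_out * val; // for dm
            // d(sampled val)/d r and /d c
            const double dvdr = (1 - ac) * (vq[1] - vq[0]) + ac * (vq[3] - vq[2]);
            const double dvdc = (1 - ar) * (vq[2] - vq[0]) + ar * (vq[3] - vq[1]);
            dr_acc += g_out * dvdr;
            dc_acc += g_out * dvdc;
            // scatter into dx: d y[ch]/d x[ch, corner] = mw * wt[q]
            const double gm = g_out * mw;
            const double wq0 = (1 - ar) * (1 - ac), wq1 = ar * (1 - ac),
                         wq2 = (1 - ar) * ac, wq3 = ar * ac;
            const double wts[4] = {wq0, wq1, wq2, wq3};
            for (int q = 0; q < 4; ++q) {
              const int rr = r0 + (q & 1), cc = c0 + (q >> 1);
              if (rr < 0 || rr >= H || cc < 0 || cc >= W || wts[q] == 0.0) continue;
              pdx[ch + (size_t)C * (rr + (size_t)H * cc)] += gm * wts[q];
            }
            (void)v;
          }
          dmp[k + K * g] += dval_sum;
          doffp[0 + 2 * (k + K * g)] += mw * dr_acc;
          doffp[1 + 2 * (k + K * g)] += mw * dc_acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["doff"] = doff, _["dm"] = dm);
}

// ---------------------------------------------------------------------------
// Selective scan (input-dependent linear state-space recurrence).
// x, delta : (C,T); A : (C,N); B, Cc : (N,T)
//   h_t = exp(delta_t * A) .* h_{t-1} + (delta_t * x_t) (x) B_t
//   y_t[c] = sum_n h_t[c,n] * Cc[n,t]
// [[Rcpp::export]]
List cpp_scan_fwd(NumericMatrix x, NumericMatrix delta, NumericMatrix A,
                  NumericMatrix B, NumericMatrix Cc, bool keep_h) {
  const int C = x.nrow(), T = x.ncol(), N = A.ncol();
  NumericMatrix y(C, T);
  NumericVector h;
  double *ph = NULL;
  if (keep_h) {
    h = NumericVector((R_xlen_t)C * N * T);
    h.attr("dim") = Dimension(C, N, T);
    ph = h.begin();
  }
  std::vector<double> hc((size_t)C * N, 0.0);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double dt = delta(c, t), xt = x(c, t);
      const double dx = dt * xt;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double a = std::exp(dt * A(c, n));
        const double hv = a * hc[c + (size_t)C * n] + dx * B(n, t);
        hc[c + (size_t)C * n] = hv;
        acc += hv * Cc(n, t);
      }
      y(c, t) = acc;
    }
    if (keep_h)
      std::memcpy(ph + (size_t)C * N * t, hc.data(), sizeof(double) * C * N);
  }
  return List::create(_["y"] = y, _["h"] = h);
}

// [[Rcpp::export]]
List cpp_scan_bwd(NumericMatrix x, NumericMatrix delta, NumericMatrix A,
                  NumericMatrix B, NumericMatrix Cc, NumericVector h,
                  NumericMatrix dy) {
  const int C = x.nrow(), T = x.ncol(), N = A.ncol();
  NumericMatrix dx(C, T), ddelta(C, T), dA(C, N), dB(N, T), dC(N, T);
  const double *ph = h.begin();
  std::vector<double> dh_carry((size_t)C * N, 0.0);
  for (int t = T - 1; t >= 0; --t) {
    const double *ht = ph + (size_t)C * N * t;
    const double *htm1 = (t > 0) ? ph + (size_t)C * N * (t - 1) : NULL;
    for (int c = 0; c < C; ++c) {
      const double dt = delta(c, t), xt = x(c, t);
      const double gy = dy(c, t);
      double ddt = 0.0, dxt = 0.0;
      for (int n = 0; n < N; ++n) {
        const size_t idx = c + (size_t)C * n;
        double dh = dh_carry[idx] + gy * Cc(n, t);
        dC(n, t) += gy * ht[idx];
        const double a = std::exp(dt * A(c, n));
        const double hprev = htm1 ? htm1[idx] : 0.0;
        const double da = dh * hprev; // d/d a
        dA(c, n) += da * dt * a;
        ddt += da * A(c, n) * a;
        // input injection: h += dt*xt*B
        ddt += dh * xt * B(n, t);
        dxt += dh * dt * B(n, t);
        dB(n, t) += dh * dt * xt;
        dh_carry[idx] = dh * a;
      }
      ddelta(c, t) = ddt;
      dx(c, t) = dxt;
    }
  }
  return List::create(_["dx"] = dx, _["ddelta"] = ddelta, _["dA"] = dA,
                      _["dB"] = dB, _["dC"] = dC);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance from every pixel to the nearest TRUE pixel. Returns +Inf when the
// mask has no TRUE pixel.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INFINITY) continue; // no parabola from empty sites
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
      continue;
    }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k; // k stays >= 0 because z[0] = -Inf
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix on) {
  const int H = on.nrow(), W = on.ncol();
  NumericMatrix out(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  // pass 1: along columns (rows direction)
  std::vector<double> tmp((size_t)H * W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = on(h, w) ? 0.0 : INFINITY;
    dt1d(f, d, H);
    for (int h = 0; h < H; ++h) tmp[h + (size_t)H * w] = d[h];
  }
  // pass 2: along rows
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) f[w] = tmp[h + (size_t)H * w];
    dt1d(f, d, W);
    for (int w = 0; w < W; ++w) out(h, w) = std::sqrt(d[w]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// zlib helpers for the PNG codec.
// [[Rcpp::export]]
RawVector cpp_zlib_compress(RawVector data, int level) {
  uLongf bound = compressBound(data.size());
  std::vector<Bytef> buf(bound);
  int rc = compress2(buf.data(), &bound, (const Bytef *)RAW(data), data.size(), level);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector out(bound);
  std::memcpy(RAW(out), buf.data(), bound);
  return out;
}

// [[Rcpp::export]]
RawVector cpp_zlib_uncompress(RawVector data, double expected_size) {
  uLongf sz = (uLongf)expected_size;
  std::vector<Bytef> buf(sz > 0 ? sz : 1);
  for (int attempt = 0; attempt < 12; ++attempt) {
    uLongf got = buf.size();
    int rc = uncompress(buf.data(), &got, (const Bytef *)RAW(data), data.size());
    if (rc == Z_OK) {
      RawVector out(got);
      std::memcpy(RAW(out), buf.data(), got);
      return out;
    }
    if (rc == Z_BUF_ERROR) { buf.resize(buf.size() * 2); continue; }
    stop("zlib decompression failed (code %d)", rc);
  }
  stop("zlib decompression failed: buffer growth exhausted");
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef *)RAW(data), data.size());
  return (double)crc;
}

// Undo PNG scanline filters. data = height * (1 + rowbytes) raw bytes
// (leading filter byte per row); bpp = bytes per pixel.
// [[Rcpp::export]]
RawVector cpp_png_unfilter(RawVector data, int height, int rowbytes, int bpp) {
  if ((R_xlen_t)height * (rowbytes + 1) != data.size())
    stop("corrupt PNG: filtered data length mismatch");
  RawVector out((R_xlen_t)height * rowbytes);
  const unsigned char *src = RAW(data);
  unsigned char *dst = RAW(out);
  for (int r = 0; r < height; ++r) {
    const int ft = src[(size_t)r * (rowbytes + 1)];
    const unsigned char *in = src + (size_t)r * (rowbytes + 1) + 1;
    unsigned char *cur = dst + (size_t)r * rowbytes;
    const unsigned char *up = (r > 0) ? dst + (size_t)(r - 1) * rowbytes : NULL;
    for (int i = 0; i < rowbytes; ++i) {
      const int a = (i >= bpp) ? cur[i - bpp] : 0;       // left
      const int b2 = up ? up[i] : 0;                     // above
      const int cc = (up && i >= bpp) ? up[i - bpp] : 0; // upper-left
      int v = in[i];
      switch (ft) {
      case 0: break;
      case 1: v += a; break;
      case 2: v += b2; break;
      case 3: v += (a + b2) / 2; break;
      case 4: {
        const int p = a + b2 - cc;
        const int pa = std::abs(p - a), pb = std::abs(p - b2), pc = std::abs(p - cc);
        v += (pa <= pb && pa <= pc) ? a : (pb <= pc ? b2 : cc);
        break;
      }
      default: stop("unsupported PNG filter type %d", ft);
      }
      cur[i] = (unsigned char)(v & 0xff);
    }
  }
  return out;
}
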