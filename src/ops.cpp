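// Dense volumetric kernels: 3x3x3 same-padded convolution (forward/backward),
// 2x2x2 max pooling, and trilinear affine resampling. Layouts follow R's
// column-major arrays: volumes are (d1, d2, d3, C, N), kernels (3, 3, 3, Cin, Cout).
// Convolution is im2col + BLAS gemm; the im2col buffer is recomputed in the
// backward pass to keep peak memory at one buffer per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims5(const NumericVector &x, int *d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("expected a 5-d array (x, y, z, channel, sample)");
  for (int i = 0; i < 5; ++i) d[i] = dm[i];
}

// cols: (nvox x 27*Cin), column j = k1 + 3*k2 + 9*k3 + 27*ci
static void im2col3(const double *xc, int d1, int d2, int d3, int Cin,
                    double *cols) {
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xch = xc + (R_xlen_t)ci * nvox;
    for (int k3 = 0; k3 < 3; ++k3)
      for (int k2 = 0; k2 < 3; ++k2)
        for (int k1 = 0; k1 < 3; ++k1) {
          const int j = k1 + 3 * k2 + 9 * k3 + 27 * ci;
          double *col = cols + (R_xlen_t)j * nvox;
          const int o1 = k1 - 1, o2 = k2 - 1, o3 = k3 - 1;
          for (int i3 = 0; i3 < d3; ++i3) {
            const int s3 = i3 + o3;
            for (int i2 = 0; i2 < d2; ++i2) {
              const int s2 = i2 + o2;
              double *dst = col + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
              if (s3 < 0 || s3 >= d3 || s2 < 0 || s2 >= d2) {
                std::fill(dst, dst + d1, 0.0);
              } else {
                const double *src =
                    xch + (R_xlen_t)d1 * (s2 + (R_xlen_t)d2 * s3);
                // i1 runs 0..d1-1, source index i1 + o1 clipped to [0, d1)
                const int lo = std::max(0, -o1);          // first valid i1
                const int hi = std::min(d1, d1 - o1);     // one past last
                for (int i1 = 0; i1 < lo; ++i1) dst[i1] = 0.0;
                for (int i1 = lo; i1 < hi; ++i1) dst[i1] = src[i1 + o1];
                for (int i1 = hi; i1 < d1; ++i1) dst[i1] = 0.0;
              }
            }
          }
        }
  }
}

// scatter-add transpose of im2col3
static void col2im3_add(const double *cols, int d1, int d2, int d3, int Cin,
                        double *xc) {
  const R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  for (int ci = 0; ci < Cin; ++ci) {
    double *xch = xc + (R_xlen_t)ci * nvox;
    for (int k3 = 0; k3 < 3; ++k3)
      for (int k2 = 0; k2 < 3; ++k2)
        for (int k1 = 0; k1 < 3; ++k1) {
          const int j = k1 + 3 * k2 + 9 * k3 + 27 * ci;
          const double *col = cols + (R_xlen_t)j * nvox;
          const int o1 = k1 - 1, o2 = k2 - 1, o3 = k3 - 1;
          for (int i3 = 0; i3 < d3; ++i3) {
            const int s3 = i3 + o3;
            if (s3 < 0 || s3 >= d3) continue;
            for (int i2 = 0; i2 < d2; ++i2) {
              const int s2 = i2 + o2;
              if (s2 < 0 || s2 >= d2) continue;
              const double *src = col + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
              double *dst = xch + (R_xlen_t)d1 * (s2 + (R_xlen_t)d2 * s3);
              const int lo = std::max(0, -o1);
              const int hi = std::min(d1, d1 - o1);
              for (int i1 = lo; i1 < hi; ++i1) dst[i1 + o1] += src[i1];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int d[5];
  get_dims5(x, d);
  IntegerVector wd = w.attr("dim");
  const int Cin = d[3], N = d[4], Cout = wd[4];
  if (wd[3] != Cin) stop("kernel input channels do not match input");
  const R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector y((R_xlen_t)nvox * Cout * N);
  y.attr("dim") = IntegerVector::create(d[0], d[1], d[2], Cout, N);
  arma::mat W(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat cols(nvox, 27 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (R_xlen_t)n * nvox * Cin, d[0], d[1], d[2], Cin,
            cols.memptr());
    arma::mat Y(y.begin() + (R_xlen_t)n * nvox * Cout, nvox, Cout, false, true);
    Y = cols * W;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int d[5];
  get_dims5(x, d);
  IntegerVector wd = w.attr("dim");
  const int Cin = d[3], N = d[4], Cout = wd[4];
  const R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat W(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat GW(gw.begin(), 27 * Cin, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat cols(nvox, 27 * Cin);
  arma::mat gcols(nvox, 27 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (R_xlen_t)n * nvox * Cin, d[0], d[1], d[2], Cin,
            cols.memptr());
    arma::mat GY(gy.begin() + (R_xlen_t)n * nvox * Cout, nvox, Cout, false,
                 true);
    GW += cols.t() * GY;
    GB += arma::sum(GY, 0).t();
    gcols = GY * W.t();
    col2im3_add(gcols.memptr(), d[0], d[1], d[2], Cin,
                gx.begin() + (R_xlen_t)n * nvox * Cin);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x) {
  int d[5];
  get_dims5(x, d);
  if (d[0] % 2 || d[1] % 2 || d[2] % 2)
    stop("maxpool3d requires even spatial dimensions");
  const int o1 = d[0] / 2, o2 = d[1] / 2, o3 = d[2] / 2;
  const int C = d[3], N = d[4];
  const R_xlen_t novox = (R_xlen_t)o1 * o2 * o3;
  NumericVector y(novox * C * N);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  NumericVector idx(novox * C * N);  // 0-based linear index into x
  const R_xlen_t nvox = (R_xlen_t)d[0] * d[1] * d[2];
  R_xlen_t p = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double *xc = x.begin() + (R_xlen_t)cn * nvox;
    const R_xlen_t base = (R_xlen_t)cn * nvox;
    for (int j3 = 0; j3 < o3; ++j3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double best = -HUGE_VAL;
          R_xlen_t bidx = 0;
          for (int a3 = 0; a3 < 2; ++a3)
            for (int a2 = 0; a2 < 2; ++a2)
              for (int a1 = 0; a1 < 2; ++a1) {
                const R_xlen_t ii = (2 * j1 + a1) +
                                    (R_xlen_t)d[0] * ((2 * j2 + a2) +
                                                      (R_xlen_t)d[1] * (2 * j3 + a3));
                const double v = xc[ii];
                if (v > best) {
                  best = v;
                  bidx = ii;
                }
              }
          y[p] = best;
          idx[p] = (double)(base + bidx);
          ++p;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, NumericVector idx,
                            IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[(R_xlen_t)idx[i]] += gy[i];
  return gx;
}

// Resample a single 3-d volume through the affine map src = A * p + b where
// p is the 0-based output voxel coordinate; trilinear interpolation, zero
// fill outside the source grid.
// [[Rcpp::export]]
NumericVector resample_affine(NumericVector vol, NumericMatrix A,
                              NumericVector b, IntegerVector outdim) {
  IntegerVector dm = vol.attr("dim");
  if (dm.size() != 3) stop("expected a 3-d volume");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int o1 = outdim[0], o2 = outdim[1], o3 = outdim[2];
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  out.attr("dim") = outdim;
  const double *v = vol.begin();
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3) return 0.0;
    return v[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
  };
  R_xlen_t p = 0;
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        const double sx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + b[0];
        const double sy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + b[1];
        const double sz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + b[2];
        const double fx = std::floor(sx), fy = std::floor(sy),
                     fz = std::floor(sz);
        const double tx = sx - fx, ty = sy - fy, tz = sz - fz;
        const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
        double acc = 0.0;
        for (int az = 0; az < 2; ++az)
          for (int ay = 0; ay < 2; ++ay)
            for (int ax = 0; ax < 2; ++ax) {
              const double wgt = (ax ? tx : 1 - tx) * (ay ? ty : 1 - ty) *
                                 (az ? tz : 1 - tz);
              if (wgt != 0.0) acc += wgt * at(x0 + ax, y0 + ay, z0 + az);
            }
        out[p++] = acc;
      }
  return out;
}
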