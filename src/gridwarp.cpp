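// Compiled kernels for the distortion-QA pipeline: trilinear sampling,
// 3D zero-normalized cross-correlation, 26-connectivity labeling,
// separable Gaussian smoothing and Chebyshev dilation, cubic B-spline
// free-form-deformation evaluation, and the stochastic metric/gradient
// engine used by the nonrigid registration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- trilinear

// x,y,z are 0-based continuous voxel coordinates; returns false outside the
// volume. Values beyond the last voxel center are not extrapolated.
static inline bool trilin(const double* v, const int* d,
                          double x, double y, double z, double* out) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= d[0] - 1.0 && y <= d[1] - 1.0 && z <= d[2] - 1.0)) return false;
  int i = (int)x, j = (int)y, k = (int)z;
  if (i > d[0] - 2) i = d[0] - 2;
  if (j > d[1] - 2) j = d[1] - 2;
  if (k > d[2] - 2) k = d[2] - 2;
  double fx = x - i, fy = y - j, fz = z - k;
  const int nx = d[0], nxy = d[0] * d[1];
  const double* p = v + (size_t)i + (size_t)j * nx + (size_t)k * nxy;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
  double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
  *out = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double fill) {
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  const int* d = dim.begin();
  for (int s = 0; s < n; ++s) {
    double val;
    out[s] = trilin(v, d, pts(s, 0), pts(s, 1), pts(s, 2), &val) ? val : fill;
  }
  return out;
}

// ------------------------------------------------------------------- ZNCC

// Zero-normalized cross-correlation of a binary template over a volume.
// Computed only where the template fully fits; the outer margin is -1.
// Local window sums come from 3D integral images; the template correlation
// sum loops over foreground voxels only.
// [[Rcpp::export]]
NumericVector cpp_zncc(NumericVector vol, IntegerVector vd,
                       NumericVector tpl, IntegerVector td) {
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int tx = td[0], ty = td[1], tz = td[2];
  const size_t nxy = (size_t)nx * ny;
  const double* v = vol.begin();

  // integral images, dims (nx+1, ny+1, nz+1)
  const size_t ix = nx + 1, ixy = (size_t)(nx + 1) * (ny + 1);
  std::vector<double> S1(ixy * (nz + 1), 0.0), S2(ixy * (nz + 1), 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double val = v[i + (size_t)j * nx + (size_t)k * nxy];
        size_t a = (i + 1) + (j + 1) * ix + (k + 1) * ixy;
        S1[a] = val + S1[a - 1] + S1[a - ix] + S1[a - ixy]
              - S1[a - 1 - ix] - S1[a - 1 - ixy] - S1[a - ix - ixy]
              + S1[a - 1 - ix - ixy];
        S2[a] = val * val + S2[a - 1] + S2[a - ix] + S2[a - ixy]
              - S2[a - 1 - ix] - S2[a - 1 - ixy] - S2[a - ix - ixy]
              + S2[a - 1 - ix - ixy];
      }

  // template foreground offsets (volume strides)
  std::vector<size_t> fg;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i)
        if (tpl[i + (size_t)j * tx + (size_t)k * tx * ty] > 0.5)
          fg.push_back((size_t)i + (size_t)j * nx + (size_t)k * nxy);

  const double ntot = (double)tx * ty * tz;
  const double nf = (double)fg.size();
  const double tvar = nf - nf * nf / ntot;  // n * var of binary template
  NumericVector out((R_xlen_t)nxy * nz, -1.0);
  if (tvar <= 0.0) return out;  // degenerate; guarded at R level too
  const double tden = std::sqrt(tvar);
  const int cx = (tx - 1) / 2, cy = (ty - 1) / 2, cz = (tz - 1) / 2;

  for (int z0 = 0; z0 + tz <= nz; ++z0)
    for (int y0 = 0; y0 + ty <= ny; ++y0)
      for (int x0 = 0; x0 + tx <= nx; ++x0) {
        size_t a111 = (x0 + tx) + (size_t)(y0 + ty) * ix + (size_t)(z0 + tz) * ixy;
        size_t a011 = x0 + (size_t)(y0 + ty) * ix + (size_t)(z0 + tz) * ixy;
        size_t a101 = (x0 + tx) + (size_t)y0 * ix + (size_t)(z0 + tz) * ixy;
        size_t a110 = (x0 + tx) + (size_t)(y0 + ty) * ix + (size_t)z0 * ixy;
        size_t a001 = x0 + (size_t)y0 * ix + (size_t)(z0 + tz) * ixy;
        size_t a010 = x0 + (size_t)(y0 + ty) * ix + (size_t)z0 * ixy;
        size_t a100 = (x0 + tx) + (size_t)y0 * ix + (size_t)z0 * ixy;
        size_t a000 = x0 + (size_t)y0 * ix + (size_t)z0 * ixy;
        double s1 = S1[a111] - S1[a011] - S1[a101] - S1[a110]
                  + S1[a001] + S1[a010] + S1[a100] - S1[a000];
        double s2 = S2[a111] - S2[a011] - S2[a101] - S2[a110]
                  + S2[a001] + S2[a010] + S2[a100] - S2[a000];
        const double* base = v + (size_t)x0 + (size_t)y0 * nx + (size_t)z0 * nxy;
        double sit = 0.0;
        for (size_t f = 0; f < fg.size(); ++f) sit += base[fg[f]];
        double num = sit - s1 * (nf / ntot);
        double ivar = s2 - s1 * s1 / ntot;
        double corr = 0.0;
        if (ivar > 1e-12) corr = num / (tden * std::sqrt(ivar));
        if (corr > 1.0) corr = 1.0;
        if (corr < -1.0) corr = -1.0;
        out[(x0 + cx) + (size_t)(y0 + cy) * nx + (size_t)(z0 + cz) * nxy] = corr;
      }
  return out;
}

// ------------------------------------------------------- connected labeling

// 26-connectivity labeling of a 3D logical mask; labels start at 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector d) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  IntegerVector lab((R_xlen_t)n, 0);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++cur;
    lab[start] = cur;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / nxy), rem = (int)(p % nxy);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            size_t q = (size_t)ii + (size_t)jj * nx + (size_t)kk * nxy;
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}

// -------------------------------------------------------- smoothing/dilation

// separable Gaussian with clamp-to-edge boundaries
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector d, NumericVector sigma) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  const size_t strides[3] = {1, (size_t)nx, nxy};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> w(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      w[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += w[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) w[i] /= sum;
    const int len = dims[ax];
    const size_t st = strides[ax];
    // iterate over all lines along axis ax
    const int d1 = dims[(ax + 1) % 3], d2 = dims[(ax + 2) % 3];
    const size_t st1 = strides[(ax + 1) % 3], st2 = strides[(ax + 2) % 3];
    for (int j2 = 0; j2 < d2; ++j2)
      for (int j1 = 0; j1 < d1; ++j1) {
        size_t base = (size_t)j1 * st1 + (size_t)j2 * st2;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = 0;
            if (ii >= len) ii = len - 1;
            acc += w[t + r] * a[base + (size_t)ii * st];
          }
          b[base + (size_t)i * st] = acc;
        }
      }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// separable Chebyshev (box) dilation with per-axis radius in voxels
// [[Rcpp::export]]
LogicalVector cpp_dilate3(LogicalVector mask, IntegerVector d, IntegerVector rad) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const size_t n = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  std::vector<char> a(n), b(n);
  for (size_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  const int dims[3] = {nx, ny, nz};
  const size_t strides[3] = {1, (size_t)nx, nxy};
  for (int ax = 0; ax < 3; ++ax) {
    int r = rad[ax];
    if (r <= 0) continue;
    const int len = dims[ax];
    const size_t st = strides[ax];
    const int d1 = dims[(ax + 1) % 3], d2 = dims[(ax + 2) % 3];
    const size_t st1 = strides[(ax + 1) % 3], st2 = strides[(ax + 2) % 3];
    for (int j2 = 0; j2 < d2; ++j2)
      for (int j1 = 0; j1 < d1; ++j1) {
        size_t base = (size_t)j1 * st1 + (size_t)j2 * st2;
        for (int i = 0; i < len; ++i) {
          char any = 0;
          int lo = i - r < 0 ? 0 : i - r;
          int hi = i + r >= len ? len - 1 : i + r;
          for (int ii = lo; ii <= hi && !any; ++ii) any = a[base + (size_t)ii * st];
          b[base + (size_t)i * st] = any;
        }
      }
    a.swap(b);
  }
  LogicalVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  return out;
}

// ------------------------------------------------------------ cubic B-spline

static inline void bspl_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// cell index for u = (x - origin)/spacing; clamped so the boundary cell's
// polynomial pieces extend the field naturally outside the support
static inline void bspl_idx(double u, int n, int* i0, double* t) {
  int i = (int)std::floor(u);
  if (i < 1) i = 1;
  if (i > n - 3) i = n - 3;
  *i0 = i;
  *t = u - i;
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, IntegerVector cshape,
                               NumericVector corig, NumericVector cspac,
                               NumericMatrix pts) {
  const int n1 = cshape[0], n2 = cshape[1], n3 = cshape[2];
  const size_t nc = (size_t)n1 * n2 * n3;
  const int N = pts.nrow();
  const double* cf = coef.begin();
  NumericMatrix out(N, 3);
  for (int s = 0; s < N; ++s) {
    double u[3];
    int i0[3];
    double t[3], w[3][4];
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(s, a) - corig[a]) / cspac[a];
      bspl_idx(u[a], cshape[a], &i0[a], &t[a]);
      bspl_w(t[a], w[a]);
    }
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = w[1][b] * w[2][c];
        size_t row = (size_t)(i0[0] - 1) +
                     (size_t)n1 * ((size_t)(i0[1] - 1 + b) + (size_t)n2 * (i0[2] - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double wt = w[0][a] * wbc;
          size_t id = row + a;
          dx += wt * cf[id];
          dy += wt * cf[id + nc];
          dz += wt * cf[id + 2 * nc];
        }
      }
    out(s, 0) = dx;
    out(s, 1) = dy;
    out(s, 2) = dz;
  }
  return out;
}

// ------------------------------------------------------------- metric engine

static inline double parzen3(double s) {
  s = std::fabs(s);
  if (s < 1.0) return (4.0 - 6.0 * s * s + 3.0 * s * s * s) / 6.0;
  if (s < 2.0) {
    double u = 2.0 - s;
    return u * u * u / 6.0;
  }
  return 0.0;
}

static inline double parzen3d(double s) {
  double as = std::fabs(s), r;
  if (as < 1.0) r = as * (3.0 * as - 4.0) / 2.0;
  else if (as < 2.0) {
    double u = 2.0 - as;
    r = -u * u / 2.0;
  } else return 0.0;
  return s < 0 ? -r : r;
}

// Value and coefficient-gradient of the similarity metric between the fixed
// (domain) volume at sample points x and the moving (target) volume at
// x + u(x), where u is the cubic B-spline FFD with the given coefficients.
// metric: 0 = mean squares, 1 = negated mutual information (Mattes-style:
// box Parzen window on the fixed axis, cubic B-spline window on the moving
// axis). Moving-image gradients are pre-computed volumes in intensity/mm.
// [[Rcpp::export]]
List cpp_metric_grad(NumericVector coef, IntegerVector cshape,
                     NumericVector corig, NumericVector cspac,
                     NumericMatrix pts,
                     NumericVector fvol, IntegerVector fdim,
                     NumericVector fspac, NumericVector forig,
                     NumericVector mvol, NumericVector mgx, NumericVector mgy,
                     NumericVector mgz, IntegerVector mdim,
                     NumericVector mspac, NumericVector morig,
                     int metric, int nbins,
                     NumericVector frange, NumericVector mrange) {
  const int n1 = cshape[0], n2 = cshape[1], n3 = cshape[2];
  const size_t nc = (size_t)n1 * n2 * n3;
  const int N = pts.nrow();
  const double* cf = coef.begin();
  NumericVector grad((R_xlen_t)nc * 3);

  std::vector<double> Fv(N), Mv(N), Gx(N), Gy(N), Gz(N);
  std::vector<double> WX(N * 4), WY(N * 4), WZ(N * 4);
  std::vector<int> I0(N), J0(N), K0(N);
  std::vector<char> ok(N, 0);
  int nvalid = 0;

  for (int s = 0; s < N; ++s) {
    double w3[3][4];
    int i0[3];
    for (int a = 0; a < 3; ++a) {
      double u = (pts(s, a) - corig[a]) / cspac[a];
      double t;
      bspl_idx(u, cshape[a], &i0[a], &t);
      bspl_w(t, w3[a]);
    }
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = w3[1][b] * w3[2][c];
        size_t row = (size_t)(i0[0] - 1) +
                     (size_t)n1 * ((size_t)(i0[1] - 1 + b) + (size_t)n2 * (i0[2] - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double wt = w3[0][a] * wbc;
          dx += wt * cf[row + a];
          dy += wt * cf[row + a + nc];
          dz += wt * cf[row + a + 2 * nc];
        }
      }
    double fx = (pts(s, 0) - forig[0]) / fspac[0];
    double fy = (pts(s, 1) - forig[1]) / fspac[1];
    double fz = (pts(s, 2) - forig[2]) / fspac[2];
    double fval;
    if (!trilin(fvol.begin(), fdim.begin(), fx, fy, fz, &fval)) continue;
    double mx = (pts(s, 0) + dx - morig[0]) / mspac[0];
    double my = (pts(s, 1) + dy - morig[1]) / mspac[1];
    double mz = (pts(s, 2) + dz - morig[2]) / mspac[2];
    double mval, gx, gy, gz;
    if (!trilin(mvol.begin(), mdim.begin(), mx, my, mz, &mval)) continue;
    trilin(mgx.begin(), mdim.begin(), mx, my, mz, &gx);
    trilin(mgy.begin(), mdim.begin(), mx, my, mz, &gy);
    trilin(mgz.begin(), mdim.begin(), mx, my, mz, &gz);
    ok[s] = 1;
    ++nvalid;
    Fv[s] = fval;
    Mv[s] = mval;
    Gx[s] = gx;
    Gy[s] = gy;
    Gz[s] = gz;
    I0[s] = i0[0];
    J0[s] = i0[1];
    K0[s] = i0[2];
    for (int a = 0; a < 4; ++a) {
      WX[s * 4 + a] = w3[0][a];
      WY[s * 4 + a] = w3[1][a];
      WZ[s * 4 + a] = w3[2][a];
    }
  }

  double value = 0.0;
  std::vector<double> fac(N, 0.0);  // dCost/dMovingValue per sample

  if (nvalid == 0)
    return List::create(_["value"] = R_PosInf, _["grad"] = grad, _["nvalid"] = 0);

  if (metric == 0) {  // mean squares
    for (int s = 0; s < N; ++s) {
      if (!ok[s]) continue;
      double diff = Mv[s] - Fv[s];
      value += diff * diff;
      fac[s] = 2.0 * diff / nvalid;
    }
    value /= nvalid;
  } else {  // negated mutual information
    const double f0 = frange[0], f1 = frange[1];
    const double m0 = mrange[0], m1 = mrange[1];
    const double mspan = (double)(nbins - 4);
    std::vector<double> H((size_t)nbins * nbins, 0.0);
    std::vector<double> U(N), DU(N, 0.0);
    std::vector<int> BF(N);
    for (int s = 0; s < N; ++s) {
      if (!ok[s]) continue;
      double m = Mv[s];
      double du = mspan / (m1 - m0);
      if (m <= m0) { m = m0; du = 0.0; }
      if (m >= m1) { m = m1; du = 0.0; }
      double u = 1.5 + (m - m0) / (m1 - m0) * mspan;
      double f = Fv[s];
      if (f < f0) f = f0;
      if (f > f1) f = f1;
      int bf = (int)((f - f0) / (f1 - f0) * nbins);
      if (bf > nbins - 1) bf = nbins - 1;
      if (bf < 0) bf = 0;
      U[s] = u;
      DU[s] = du;
      BF[s] = bf;
      int lo = (int)std::ceil(u - 2.0), hi = (int)std::floor(u + 2.0);
      if (lo < 0) lo = 0;
      if (hi > nbins - 1) hi = nbins - 1;
      for (int mb = lo; mb <= hi; ++mb)
        H[(size_t)BF[s] + (size_t)nbins * mb] += parzen3(u - mb);
    }
    std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
    double tot = 0.0;
    for (size_t i = 0; i < H.size(); ++i) tot += H[i];
    for (int mb = 0; mb < nbins; ++mb)
      for (int fb = 0; fb < nbins; ++fb) {
        double p = H[(size_t)fb + (size_t)nbins * mb] / tot;
        H[(size_t)fb + (size_t)nbins * mb] = p;
        pf[fb] += p;
        pm[mb] += p;
      }
    double mi = 0.0;
    for (int mb = 0; mb < nbins; ++mb)
      for (int fb = 0; fb < nbins; ++fb) {
        double p = H[(size_t)fb + (size_t)nbins * mb];
        if (p > 1e-14) mi += p * std::log(p / (pf[fb] * pm[mb]));
      }
    value = -mi;
    for (int s = 0; s < N; ++s) {
      if (!ok[s] || DU[s] == 0.0) continue;
      double u = U[s];
      int bf = BF[s];
      int lo = (int)std::ceil(u - 2.0), hi = (int)std::floor(u + 2.0);
      if (lo < 0) lo = 0;
      if (hi > nbins - 1) hi = nbins - 1;
      double acc = 0.0;
      for (int mb = lo; mb <= hi; ++mb) {
        double p = H[(size_t)bf + (size_t)nbins * mb];
        if (p > 1e-14 && pm[mb] > 1e-14)
          acc += parzen3d(u - mb) * std::log(p / (pf[bf] * pm[mb]));
      }
      fac[s] = -acc * DU[s] / tot;
    }
  }

  for (int s = 0; s < N; ++s) {
    if (!ok[s] || fac[s] == 0.0) continue;
    double fxv = fac[s] * Gx[s], fyv = fac[s] * Gy[s], fzv = fac[s] * Gz[s];
    const double* wx = &WX[s * 4];
    const double* wy = &WY[s * 4];
    const double* wz = &WZ[s * 4];
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wbc = wy[b] * wz[c];
        size_t row = (size_t)(I0[s] - 1) +
                     (size_t)n1 * ((size_t)(J0[s] - 1 + b) + (size_t)n2 * (K0[s] - 1 + c));
        for (int a = 0; a < 4; ++a) {
          double wt = wx[a] * wbc;
          grad[row + a] += wt * fxv;
          grad[row + a + nc] += wt * fyv;
          grad[row + a + 2 * nc] += wt * fzv;
        }
      }
  }

  return List::create(_["value"] = value, _["grad"] = grad, _["nvalid"] = nvalid);
}

// Mutual information between two paired intensity vectors (linear Parzen
// spreading on both axes); used by the rigid pre-alignment.
// [[Rcpp::export]]
double cpp_mi_pair(NumericVector a, NumericVector b, int nbins) {
  const int n = a.size();
  double a0 = R_PosInf, a1 = R_NegInf, b0 = R_PosInf, b1 = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (a[i] < a0) a0 = a[i];
    if (a[i] > a1) a1 = a[i];
    if (b[i] < b0) b0 = b[i];
    if (b[i] > b1) b1 = b[i];
  }
  if (!(a1 > a0) || !(b1 > b0)) return 0.0;
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  const double sa = (nbins - 1) / (a1 - a0), sb = (nbins - 1) / (b1 - b0);
  for (int i = 0; i < n; ++i) {
    double ua = (a[i] - a0) * sa, ub = (b[i] - b0) * sb;
    int ia = (int)ua, ib = (int)ub;
    if (ia > nbins - 2) ia = nbins - 2;
    if (ib > nbins - 2) ib = nbins - 2;
    double fa = ua - ia, fb = ub - ib;
    H[(size_t)ia + (size_t)nbins * ib] += (1 - fa) * (1 - fb);
    H[(size_t)ia + 1 + (size_t)nbins * ib] += fa * (1 - fb);
    H[(size_t)ia + (size_t)nbins * (ib + 1)] += (1 - fa) * fb;
    H[(size_t)ia + 1 + (size_t)nbins * (ib + 1)] += fa * fb;
  }
  std::vector<double> pa(nbins, 0.0), pb(nbins, 0.0);
  for (int jb = 0; jb < nbins; ++jb)
    for (int ja = 0; ja < nbins; ++ja) {
      double p = H[(size_t)ja + (size_t)nbins * jb] / n;
      H[(size_t)ja + (size_t)nbins * jb] = p;
      pa[ja] += p;
      pb[jb] += p;
    }
  double mi = 0.0;
  for (int jb = 0; jb < nbins; ++jb)
    for (int ja = 0; ja < nbins; ++ja) {
      double p = H[(size_t)ja + (size_t)nbins * jb];
      if (p > 1e-14) mi += p * std::log(p / (pa[ja] * pb[jb]));
    }
  return mi;
}
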