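// Numerical kernels: separable 3D convolution, cubic B-spline resampling,
// grey-level co-occurrence / run-length accumulation, first-order statistics,
// and marching-tetrahedra surface meshing. All grids are column-major
// (R array layout), 0-based inside C++.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // half-sample reflection: (d c b a | a b c d | d c b a)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline int mirror_idx(int i, int n) {
  // whole-sample mirror: (c b | a b c d | c b) — matches the recursive
  // B-spline prefilter's boundary assumption
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Correlate along one axis (0=x, 1=y, 2=z) with reflect padding.
// `center` gives the tap index aligned with the output voxel.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector f, int axis, int center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = f.size();
  NumericVector out(x.size());
  const double *px = x.begin(), *pf = f.begin();
  double *po = out.begin();
  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, (long)nx, (long)nx * ny};
  const int na = n[axis];
  const long sa = stride[axis];
  // iterate over all lines along `axis`
  const int b1 = axis == 0 ? 1 : 0;
  const int b2 = axis == 2 ? 1 : 2;
  for (int k = 0; k < n[b2]; ++k) {
    for (int j = 0; j < n[b1]; ++j) {
      const long base = (long)j * stride[b1] + (long)k * stride[b2];
      const int lo = center;
      const int hi = na - (nf - 1 - center);
      int i = 0;
      for (; i < lo && i < na; ++i) {
        double acc = 0.0;
        for (int t = 0; t < nf; ++t)
          acc += pf[t] * px[base + (long)reflect_idx(i + t - center, na) * sa];
        po[base + (long)i * sa] = acc;
      }
      for (; i < hi; ++i) {            // interior: no boundary handling
        double acc = 0.0;
        const long b0 = base + (long)(i - center) * sa;
        for (int t = 0; t < nf; ++t)
          acc += pf[t] * px[b0 + (long)t * sa];
        po[base + (long)i * sa] = acc;
      }
      for (; i < na; ++i) {
        double acc = 0.0;
        for (int t = 0; t < nf; ++t)
          acc += pf[t] * px[base + (long)reflect_idx(i + t - center, na) * sa];
        po[base + (long)i * sa] = acc;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cubic B-spline interpolation (Unser recursive prefilter, reflect boundary)
// ---------------------------------------------------------------------------
static void bspline_prefilter_line(double *c, int n, long stride) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;      // pole of the cubic B-spline
  const double gain = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[(long)i * stride] *= gain;
  // causal initialisation (mirror boundary, truncated horizon)
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = c[0], zn = z;
  for (int i = 1; i < horizon; ++i) { sum += zn * c[(long)i * stride]; zn *= z; }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[(long)i * stride] += z * c[(long)(i - 1) * stride];
  // anti-causal
  c[(long)(n - 1) * stride] =
    (z / (z * z - 1.0)) * (c[(long)(n - 1) * stride] + z * c[(long)(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[(long)i * stride] = z * (c[(long)(i + 1) * stride] - c[(long)i * stride]);
}

static void bspline_weights(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Resample to isotropic `target` spacing; cubic B-spline interpolation.
// Output grid: n_out = max(1, round(n_in * spacing / target)); output voxel
// centres map to input coordinates u = (i + 0.5) * target/spacing - 0.5.
// [[Rcpp::export]]
List cpp_resample_bspline(NumericVector x, IntegerVector dim,
                          NumericVector spacing, double target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> c(x.begin(), x.end());
  // prefilter along each axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      bspline_prefilter_line(&c[(long)j * nx + (long)k * nx * ny], nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      bspline_prefilter_line(&c[(long)i + (long)k * nx * ny], ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      bspline_prefilter_line(&c[(long)i + (long)j * nx], nz, (long)nx * ny);

  IntegerVector odim(3);
  for (int a = 0; a < 3; ++a)
    odim[a] = std::max(1, (int)std::lround(dim[a] * spacing[a] / target));
  const int mx = odim[0], my = odim[1], mz = odim[2];
  NumericVector out((long)mx * my * mz);
  double *po = out.begin();

  // per-axis index/weight tables
  std::vector<int> ix(4 * mx), iy(4 * my), iz(4 * mz);
  std::vector<double> wx(4 * mx), wy(4 * my), wz(4 * mz);
  const int nn[3] = {nx, ny, nz};
  const int mm[3] = {mx, my, mz};
  std::vector<int> *itab[3] = {&ix, &iy, &iz};
  std::vector<double> *wtab[3] = {&wx, &wy, &wz};
  for (int a = 0; a < 3; ++a) {
    for (int i = 0; i < mm[a]; ++i) {
      double u = (i + 0.5) * target / spacing[a] - 0.5;
      if (u < 0) u = 0;
      if (u > nn[a] - 1) u = nn[a] - 1;
      int fl = (int)std::floor(u);
      if (fl > nn[a] - 2) fl = nn[a] - 2;
      if (fl < 0) fl = 0;
      double t = u - fl;
      double w[4];
      bspline_weights(t, w);
      for (int q = 0; q < 4; ++q) {
        (*itab[a])[4 * i + q] = mirror_idx(fl - 1 + q, nn[a]);
        (*wtab[a])[4 * i + q] = w[q];
      }
    }
  }
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0.0;
        for (int qz = 0; qz < 4; ++qz) {
          const long oz = (long)iz[4 * k + qz] * nx * ny;
          double accz = 0.0;
          for (int qy = 0; qy < 4; ++qy) {
            const long oy = (long)iy[4 * j + qy] * nx + oz;
            double accy = 0.0;
            for (int qx = 0; qx < 4; ++qx)
              accy += wx[4 * i + qx] * c[oy + ix[4 * i + qx]];
            accz += wy[4 * j + qy] * accy;
          }
          acc += wz[4 * k + qz] * accz;
        }
        po[(long)i + (long)mx * (j + (long)my * k)] = acc;
      }
  return List::create(_["values"] = out, _["dim"] = odim);
}

// Nearest-neighbour resampling on the same output grid (for masks).
// [[Rcpp::export]]
List cpp_resample_nn(IntegerVector x, IntegerVector dim,
                     NumericVector spacing, double target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector odim(3);
  for (int a = 0; a < 3; ++a)
    odim[a] = std::max(1, (int)std::lround(dim[a] * spacing[a] / target));
  const int mx = odim[0], my = odim[1], mz = odim[2];
  IntegerVector out((long)mx * my * mz);
  const int nn[3] = {nx, ny, nz};
  const int mm[3] = {mx, my, mz};
  std::vector<int> idx[3];
  for (int a = 0; a < 3; ++a) {
    idx[a].resize(mm[a]);
    for (int i = 0; i < mm[a]; ++i) {
      double u = (i + 0.5) * target / spacing[a] - 0.5;
      int r = (int)std::lround(u);
      if (r < 0) r = 0;
      if (r > nn[a] - 1) r = nn[a] - 1;
      idx[a][i] = r;
    }
  }
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i)
        out[(long)i + (long)mx * (j + (long)my * k)] =
          x[(long)idx[0][i] + (long)nx * (idx[1][j] + (long)ny * idx[2][k])];
  return List::create(_["values"] = out, _["dim"] = odim);
}

// ---------------------------------------------------------------------------
// Texture matrices. `lev` holds the discretised grey level (1..ng) inside the
// ROI and 0 outside. 13 unique 3D offsets (distance 1, 26-connectivity).
// ---------------------------------------------------------------------------
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

struct SparseAccum {
  std::vector<double> buf;
  std::vector<long> touched;
  void init(long size) { buf.assign(size, 0.0); touched.clear(); }
  void reset() { for (long t : touched) buf[t] = 0.0; touched.clear(); }
  inline void add(long idx, double v) {
    if (buf[idx] == 0.0) touched.push_back(idx);
    buf[idx] += v;
  }
};

// GLCM features, direction-averaged over the 13 symmetric co-occurrence
// matrices at distance 1. Returns 24 values in fixed order.
// `logtab` caches log(c) for integer counts (entropy terms), shared across
// directions.
static void glcm_one_dir(const SparseAccum &acc, int ng, double total,
                         std::vector<double> &logtab, double feat[24]);

// Count of eigenvalues of the symmetric tridiagonal (alpha, beta) below x
// (Sturm sequence), for bisection.
static int sturm_count(const std::vector<double> &alpha,
                       const std::vector<double> &beta, int m, double x) {
  int cnt = 0;
  double q = alpha[0] - x;
  if (q < 0) ++cnt;
  for (int i = 1; i < m; ++i) {
    double b2 = beta[i - 1] * beta[i - 1];
    if (std::fabs(q) < 1e-300) q = q < 0 ? -1e-300 : 1e-300;
    q = alpha[i] - x - b2 / q;
    if (q < 0) ++cnt;
  }
  return cnt;
}

static double tridiag_extreme(const std::vector<double> &alpha,
                              const std::vector<double> &beta, int m,
                              bool largest) {
  double lo = alpha[0], hi = alpha[0];
  for (int i = 0; i < m; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(beta[i - 1]);
    if (i < m - 1) r += std::fabs(beta[i]);
    lo = std::min(lo, alpha[i] - r);
    hi = std::max(hi, alpha[i] + r);
  }
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    int c = sturm_count(alpha, beta, m, mid);
    if (largest) { if (c >= m) hi = mid; else lo = mid; }
    else         { if (c >= 1) hi = mid; else lo = mid; }
  }
  return 0.5 * (lo + hi);
}

// Spectral radius of the deflated transition operator via a fixed-step
// Lanczos recursion (deterministic start vector, no reorthogonalisation;
// exact when the step count reaches the matrix dimension).
// `cx` holds the marginal level counts: p/sqrt(px_i px_j) = c/sqrt(cx_i cx_j).
static double mcc_lanczos(const SparseAccum &acc, const std::vector<double> &cx,
                          int ng, double total) {
  if (ng <= 1) return 1.0;
  const size_t nnz = acc.touched.size();
  std::vector<int> ei(nnz), ej(nnz);
  std::vector<double> ev(nnz);
  std::vector<double> isq(ng, 0.0);
  for (int i = 0; i < ng; ++i)
    if (cx[i] > 0) isq[i] = 1.0 / std::sqrt(cx[i]);
  size_t q = 0;
  for (long t : acc.touched) {
    int i = (int)(t / ng), j = (int)(t % ng);
    ei[q] = i; ej[q] = j;
    ev[q] = acc.buf[t] * isq[i] * isq[j];
    ++q;
  }
  std::vector<double> u(ng);
  for (int i = 0; i < ng; ++i)
    u[i] = cx[i] > 0 ? std::sqrt(cx[i] / total) : 0.0;
  const int msteps = std::min(ng, 10);
  std::vector<double> alpha(msteps, 0.0), beta(msteps, 0.0);
  std::vector<double> v(ng), vprev(ng, 0.0), w(ng);
  // deterministic start, deflated against u and normalised
  double du = 0.0, vn = 0.0;
  for (int i = 0; i < ng; ++i) v[i] = 1.0 / (i + 1.0);
  for (int i = 0; i < ng; ++i) du += v[i] * u[i];
  for (int i = 0; i < ng; ++i) { v[i] -= du * u[i]; vn += v[i] * v[i]; }
  vn = std::sqrt(vn);
  if (vn < 1e-14) return 0.0;
  for (int i = 0; i < ng; ++i) v[i] /= vn;
  int m_used = 0;
  for (int s = 0; s < msteps; ++s) {
    // w = P M P v  (v is already u-orthogonal)
    std::fill(w.begin(), w.end(), 0.0);
    for (size_t e = 0; e < nnz; ++e) w[ei[e]] += ev[e] * v[ej[e]];
    du = 0.0;
    for (int i = 0; i < ng; ++i) du += w[i] * u[i];
    for (int i = 0; i < ng; ++i) w[i] -= du * u[i];
    double a = 0.0;
    for (int i = 0; i < ng; ++i) a += v[i] * w[i];
    alpha[s] = a;
    for (int i = 0; i < ng; ++i)
      w[i] -= a * v[i] + (s > 0 ? beta[s - 1] * vprev[i] : 0.0);
    double b = 0.0;
    for (int i = 0; i < ng; ++i) b += w[i] * w[i];
    b = std::sqrt(b);
    m_used = s + 1;
    if (b < 1e-12) break;
    beta[s] = b;
    for (int i = 0; i < ng; ++i) { vprev[i] = v[i]; v[i] = w[i] / b; }
  }
  double hi = tridiag_extreme(alpha, beta, m_used, true);
  double lo = tridiag_extreme(alpha, beta, m_used, false);
  double lam = std::max(std::fabs(hi), std::fabs(lo));
  return lam > 1.0 ? 1.0 : lam;
}

// collect linear indices and coordinates of ROI voxels (level > 0)
static void roi_voxels(const int *pl, int nx, int ny, int nz,
                       std::vector<long> &lin, std::vector<int> &ci,
                       std::vector<int> &cj, std::vector<int> &ck) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long t = (long)i + (long)nx * (j + (long)ny * k);
        if (pl[t]) { lin.push_back(t); ci.push_back(i); cj.push_back(j);
                     ck.push_back(k); }
      }
}

// [[Rcpp::export]]
NumericVector cpp_glcm_features(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *pl = lev.begin();
  SparseAccum acc;
  acc.init((long)ng * ng);
  NumericVector out(24);
  std::vector<double> sums(24, 0.0);
  std::vector<double> logtab((long)lev.size() * 2 + 2, -1.0);
  std::vector<long> lin; std::vector<int> ci, cj, ck;
  roi_voxels(pl, nx, ny, nz, lin, ci, cj, ck);
  const size_t nv = lin.size();
  int used_dirs = 0;
  for (int d = 0; d < 13; ++d) {
    acc.reset();
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    const long off = (long)dx + (long)nx * (dy + (long)ny * dz);
    double total = 0.0;
    for (size_t v = 0; v < nv; ++v) {
      int i2 = ci[v] + dx, j2 = cj[v] + dy, k2 = ck[v] + dz;
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
        continue;
      int b = pl[lin[v] + off];
      if (!b) continue;
      int a = pl[lin[v]];
      // symmetrise: count both (a,b) and (b,a)
      acc.add((long)(a - 1) * ng + (b - 1), 1.0);
      acc.add((long)(b - 1) * ng + (a - 1), 1.0);
      total += 2.0;
    }
    if (total == 0.0) continue;
    double feat[24];
    glcm_one_dir(acc, ng, total, logtab, feat);
    for (int q = 0; q < 24; ++q) sums[q] += feat[q];
    ++used_dirs;
  }
  if (used_dirs == 0) stop("GLCM: no voxel pairs in any direction");
  for (int q = 0; q < 24; ++q) out[q] = sums[q] / used_dirs;
  return out;
}

static void glcm_one_dir(const SparseAccum &acc, int ng, double total,
                         std::vector<double> &logtab, double feat[24]) {
  const double LOG2 = std::log(2.0);
  // counts are integers; cache their logs
  auto ilog = [&](double c) -> double {
    long ci = (long)(c + 0.5);
    if ((size_t)ci >= logtab.size()) return std::log(c);
    if (logtab[ci] < 0) logtab[ci] = std::log((double)ci);
    return logtab[ci];
  };
  const double logT = std::log(total);
  std::vector<double> cx(ng, 0.0), csum(2 * ng, 0.0), cdiff(ng, 0.0);
  double mu = 0.0;
  for (long t : acc.touched) {
    double c = acc.buf[t];
    int i = (int)(t / ng), j = (int)(t % ng);      // 0-based levels
    cx[i] += c;
    csum[i + j] += c;                               // i+j in 0..2ng-2
    cdiff[std::abs(i - j)] += c;
    mu += (i + 1) * c;
  }
  mu /= total;
  double sig2 = 0.0, hx = 0.0;
  for (int i = 0; i < ng; ++i)
    if (cx[i] > 0) {
      double p = cx[i] / total;
      sig2 += (i + 1 - mu) * (i + 1 - mu) * p;
      hx -= p * (ilog(cx[i]) - logT) / LOG2;
    }
  double autoc = 0, clprom = 0, clshade = 0, cltend = 0, contrast = 0;
  double je = 0, jent = 0, idm = 0, idmn = 0, id = 0, idn = 0, invvar = 0;
  double maxc = 0, sumsq = 0;
  for (long t : acc.touched) {
    double c = acc.buf[t], p = c / total;
    int i = (int)(t / ng) + 1, j = (int)(t % ng) + 1;
    double s = i + j - 2.0 * mu, dd = (double)(i - j), ad = std::fabs(dd);
    double s2 = s * s, d2 = dd * dd;
    autoc += (double)i * j * p;
    clprom += s2 * s2 * p;
    clshade += s2 * s * p;
    cltend += s2 * p;
    contrast += d2 * p;
    je += p * p;
    jent -= p * (ilog(c) - logT) / LOG2;
    idm += p / (1.0 + d2);
    idmn += p / (1.0 + d2 / ((double)ng * ng));
    id += p / (1.0 + ad);
    idn += p / (1.0 + ad / ng);
    if (i != j) invvar += p / d2;
    if (c > maxc) maxc = c;
    sumsq += (i - mu) * (i - mu) * p;
  }
  double maxp = maxc / total;
  double da = 0, dent = 0;
  for (int k = 0; k < ng; ++k)
    if (cdiff[k] > 0) {
      double p = cdiff[k] / total;
      da += k * p;
      dent -= p * (ilog(cdiff[k]) - logT) / LOG2;
    }
  double dvar = 0;
  for (int k = 0; k < ng; ++k)
    if (cdiff[k] > 0) dvar += (k - da) * (k - da) * cdiff[k] / total;
  double sa = 0, sent = 0;
  for (int k = 0; k < 2 * ng - 1; ++k)
    if (csum[k] > 0) {
      double p = csum[k] / total;
      sa += (k + 2) * p;
      sent -= p * (ilog(csum[k]) - logT) / LOG2;
    }
  double corr = sig2 > 1e-12 ? (autoc - mu * mu) / sig2 : 1.0;
  // HXY1 = HXY2 = HX + HY = 2*HX exactly (symmetric marginals)
  double hxy1 = 2.0 * hx;
  double imc1 = hx > 0 ? (jent - hxy1) / hx : 0.0;
  double imc2v = 1.0 - std::exp(-2.0 * (hxy1 - jent));
  double imc2 = imc2v > 0 ? std::sqrt(imc2v) : 0.0;

  // Maximal correlation coefficient: second-largest |eigenvalue| of
  // M = D^{-1/2} P D^{-1/2} (symmetric, sparse); the top eigenpair is
  // (1, sqrt(px)) analytically, so work with the deflated operator
  // P_u M P_u (P_u = I - uu') and take its spectral radius by Lanczos.
  double mcc = mcc_lanczos(acc, cx, ng, total);

  feat[0] = autoc;   feat[1] = mu;      feat[2] = clprom;  feat[3] = clshade;
  feat[4] = cltend;  feat[5] = contrast; feat[6] = corr;   feat[7] = da;
  feat[8] = dent;    feat[9] = dvar;    feat[10] = je;     feat[11] = jent;
  feat[12] = imc1;   feat[13] = imc2;   feat[14] = idm;    feat[15] = idmn;
  feat[16] = id;     feat[17] = idn;    feat[18] = invvar; feat[19] = mcc;
  feat[20] = maxp;   feat[21] = sa;     feat[22] = sent;   feat[23] = sumsq;
}

// Normalised symmetric co-occurrence probabilities per direction, as triplets.
// [[Rcpp::export]]
DataFrame cpp_glcm_triplets(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *pl = lev.begin();
  std::vector<int> od, oi, oj;
  std::vector<double> op;
  SparseAccum acc;
  acc.init((long)ng * ng);
  std::vector<long> lin; std::vector<int> ci, cj, ck;
  roi_voxels(pl, nx, ny, nz, lin, ci, cj, ck);
  const size_t nv = lin.size();
  for (int d = 0; d < 13; ++d) {
    acc.reset();
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    const long off = (long)dx + (long)nx * (dy + (long)ny * dz);
    double total = 0.0;
    for (size_t v = 0; v < nv; ++v) {
      int i2 = ci[v] + dx, j2 = cj[v] + dy, k2 = ck[v] + dz;
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
        continue;
      int b = pl[lin[v] + off];
      if (!b) continue;
      int a = pl[lin[v]];
      acc.add((long)(a - 1) * ng + (b - 1), 1.0);
      acc.add((long)(b - 1) * ng + (a - 1), 1.0);
      total += 2.0;
    }
    if (total == 0.0) continue;
    std::vector<long> tt(acc.touched);
    std::sort(tt.begin(), tt.end());
    for (long t : tt) {
      od.push_back(d + 1);
      oi.push_back((int)(t / ng) + 1);
      oj.push_back((int)(t % ng) + 1);
      op.push_back(acc.buf[t] / total);
    }
  }
  return DataFrame::create(_["direction"] = od, _["i"] = oi, _["j"] = oj,
                           _["p"] = op);
}

// ---------------------------------------------------------------------------
// GLRLM: maximal collinear same-level runs, 13 directions, feature-averaged.
// ---------------------------------------------------------------------------
static void glrlm_runs(const int *pl, int nx, int ny, int nz, int d,
                       const std::vector<long> &lin, const std::vector<int> &ci,
                       const std::vector<int> &cj, const std::vector<int> &ck,
                       SparseAccum &acc, int maxlen, double &nr, double &np) {
  const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
  nr = 0.0; np = (double)lin.size();
  for (size_t v = 0; v < lin.size(); ++v) {
    const int i = ci[v], j = cj[v], k = ck[v];
    const int a = pl[lin[v]];
    // run start: predecessor along -d is outside grid/ROI or differs
    int ip = i - dx, jp = j - dy, kp = k - dz;
    bool start = ip < 0 || ip >= nx || jp < 0 || jp >= ny ||
                 kp < 0 || kp >= nz ||
                 pl[(long)ip + (long)nx * (jp + (long)ny * kp)] != a;
    if (!start) continue;
    int len = 1, ic = i + dx, jc = j + dy, kc = k + dz;
    while (ic >= 0 && ic < nx && jc >= 0 && jc < ny && kc >= 0 && kc < nz &&
           pl[(long)ic + (long)nx * (jc + (long)ny * kc)] == a) {
      ++len; ic += dx; jc += dy; kc += dz;
    }
    acc.add((long)(a - 1) * maxlen + (len - 1), 1.0);
    nr += 1.0;
  }
}

// 16 run-length features, direction-averaged.
// [[Rcpp::export]]
NumericVector cpp_glrlm_features(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  const int *pl = lev.begin();
  const double LOG2 = std::log(2.0);
  SparseAccum acc;
  acc.init((long)ng * maxlen);
  std::vector<double> sums(16, 0.0);
  std::vector<long> lin; std::vector<int> ci, cj, ck;
  roi_voxels(pl, nx, ny, nz, lin, ci, cj, ck);
  int used = 0;
  for (int d = 0; d < 13; ++d) {
    acc.reset();
    double nr, np;
    glrlm_runs(pl, nx, ny, nz, d, lin, ci, cj, ck, acc, maxlen, nr, np);
    if (nr == 0.0) continue;
    std::vector<double> gl(ng, 0.0), rl(maxlen, 0.0);
    double sre = 0, lre = 0, lgl = 0, hgl = 0, srl = 0, srh = 0, lrl = 0,
           lrh = 0, mu_g = 0, mu_r = 0, rent = 0;
    for (long t : acc.touched) {
      double c = acc.buf[t];
      int i = (int)(t / maxlen) + 1, j = (int)(t % maxlen) + 1;
      double i2 = (double)i * i, j2 = (double)j * j;
      gl[i - 1] += c; rl[j - 1] += c;
      sre += c / j2; lre += c * j2; lgl += c / i2; hgl += c * i2;
      srl += c / (i2 * j2); srh += c * i2 / j2; lrl += c * j2 / i2;
      lrh += c * i2 * j2;
      double p = c / nr;
      mu_g += p * i; mu_r += p * j;
      rent -= p * std::log(p) / LOG2;
    }
    double gln = 0, rln = 0;
    for (int i = 0; i < ng; ++i) gln += gl[i] * gl[i];
    for (int j = 0; j < maxlen; ++j) rln += rl[j] * rl[j];
    double glv = 0, rv = 0;
    for (long t : acc.touched) {
      double p = acc.buf[t] / nr;
      int i = (int)(t / maxlen) + 1, j = (int)(t % maxlen) + 1;
      glv += p * (i - mu_g) * (i - mu_g);
      rv += p * (j - mu_r) * (j - mu_r);
    }
    double f[16] = {sre / nr, lre / nr, gln / nr, gln / (nr * nr), rln / nr,
                    rln / (nr * nr), nr / np, glv, rv, rent, lgl / nr,
                    hgl / nr, srl / nr, srh / nr, lrl / nr, lrh / nr};
    for (int q = 0; q < 16; ++q) sums[q] += f[q];
    ++used;
  }
  if (used == 0) stop("GLRLM: no runs in any direction");
  NumericVector out(16);
  for (int q = 0; q < 16; ++q) out[q] = sums[q] / used;
  return out;
}

// Run counts P(i,j) per direction as triplets, with N_r per direction.
// [[Rcpp::export]]
List cpp_glrlm_triplets(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  const int *pl = lev.begin();
  std::vector<int> od, oi, oj;
  std::vector<double> oc;
  NumericVector nr_out(13), np_out(13);
  SparseAccum acc;
  acc.init((long)ng * maxlen);
  std::vector<long> lin; std::vector<int> ci, cj, ck;
  roi_voxels(pl, nx, ny, nz, lin, ci, cj, ck);
  for (int d = 0; d < 13; ++d) {
    acc.reset();
    double nr, np;
    glrlm_runs(pl, nx, ny, nz, d, lin, ci, cj, ck, acc, maxlen, nr, np);
    nr_out[d] = nr; np_out[d] = np;
    std::vector<long> tt(acc.touched);
    std::sort(tt.begin(), tt.end());
    for (long t : tt) {
      od.push_back(d + 1);
      oi.push_back((int)(t / maxlen) + 1);
      oj.push_back((int)(t % maxlen) + 1);
      oc.push_back(acc.buf[t]);
    }
  }
  return List::create(
    _["triplets"] = DataFrame::create(_["direction"] = od, _["i"] = oi,
                                      _["j"] = oj, _["count"] = oc),
    _["n_runs"] = nr_out, _["n_voxels"] = np_out);
}

// ---------------------------------------------------------------------------
// First-order statistics (18) on raw ROI intensities + discretised levels.
// Percentiles use linear interpolation (R type-7 convention).
// ---------------------------------------------------------------------------
static double quantile7(const std::vector<double> &s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_firstorder(NumericVector vals, IntegerVector lev, int ng,
                             double voxel_volume) {
  const int n = vals.size();
  if (n < 1) stop("empty ROI");
  const double LOG2 = std::log(2.0);
  double sum = 0, sum2 = 0;
  for (int i = 0; i < n; ++i) { sum += vals[i]; sum2 += vals[i] * vals[i]; }
  double mean = sum / n;
  double m2 = 0, m3 = 0, m4 = 0, mad = 0;
  for (int i = 0; i < n; ++i) {
    double d = vals[i] - mean;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
    mad += std::fabs(d);
  }
  m2 /= n; m3 /= n; m4 /= n; mad /= n;
  std::vector<double> s(vals.begin(), vals.end());
  std::sort(s.begin(), s.end());
  double p10 = quantile7(s, 0.10), p25 = quantile7(s, 0.25);
  double p50 = quantile7(s, 0.50), p75 = quantile7(s, 0.75);
  double p90 = quantile7(s, 0.90);
  // robust MAD: mean absolute deviation of values within [P10, P90]
  double rsum = 0; int rn = 0;
  for (int i = 0; i < n; ++i)
    if (vals[i] >= p10 && vals[i] <= p90) { rsum += vals[i]; ++rn; }
  double rmean = rn > 0 ? rsum / rn : mean, rmad = 0;
  if (rn > 0) {
    for (int i = 0; i < n; ++i)
      if (vals[i] >= p10 && vals[i] <= p90) rmad += std::fabs(vals[i] - rmean);
    rmad /= rn;
  }
  // entropy / uniformity on discretised levels
  std::vector<double> plev(ng, 0.0);
  for (int i = 0; i < n; ++i) plev[lev[i] - 1] += 1.0;
  double ent = 0, unif = 0;
  for (int g = 0; g < ng; ++g)
    if (plev[g] > 0) {
      double p = plev[g] / n;
      ent -= p * std::log(p) / LOG2;
      unif += p * p;
    }
  double skew = m2 > 1e-30 ? m3 / std::pow(m2, 1.5) : R_NaN;
  double kurt = m2 > 1e-30 ? m4 / (m2 * m2) : R_NaN;
  NumericVector out = NumericVector::create(
    sum2, voxel_volume * sum2, ent, s[0], p10, p90, s[n - 1], mean, p50,
    p75 - p25, s[n - 1] - s[0], mad, rmad, std::sqrt(sum2 / n), skew, kurt,
    m2, unif);
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field sampled at voxel centres (physical
// spacing). Vertices are placed by linear interpolation along tetrahedron
// edges at the iso level. Returns closed-surface area and enclosed
// (divergence-theorem) volume. The grid is padded by one background layer so
// the surface closes at the image boundary.
// ---------------------------------------------------------------------------
struct V3 { double x, y, z; };
static inline V3 vsub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 vcross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 vmid(V3 a, V3 b) {
  return {(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2};
}

static void add_tri(V3 a, V3 b, V3 c, V3 inward, V3 outward,
                    double &area, double &vol6) {
  V3 n = vcross(vsub(b, a), vsub(c, a));
  // orient the normal from the inside corners toward the outside corners
  if (vdot(n, vsub(outward, inward)) < 0) { V3 t = b; b = c; c = t;
                                            n = vcross(vsub(b, a), vsub(c, a)); }
  area += 0.5 * std::sqrt(vdot(n, n));
  vol6 += vdot(a, vcross(b, c));
}

static inline V3 iso_vertex(V3 a, V3 b, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// [[Rcpp::export]]
List cpp_mesh_shape(NumericVector field, IntegerVector dim,
                    NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *pf = field.begin();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // padded accessor: outside the grid is background (field value 0)
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0.0;
    return pf[(long)i + (long)nx * (j + (long)ny * k)];
  };
  static const int CORNER[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int TETS[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double area = 0.0, vol6 = 0.0;
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        double cv[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = at(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]);
          if (cv[c] > iso) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        V3 cp[8];
        for (int c = 0; c < 8; ++c)
          cp[c] = {(i + CORNER[c][0]) * sx, (j + CORNER[c][1]) * sy,
                   (k + CORNER[c][2]) * sz};
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[TETS[t][c]] > iso) in_idx[ni++] = TETS[t][c];
            else out_idx[no++] = TETS[t][c];
          }
          if (ni == 0 || ni == 4) continue;
          V3 ic = {0,0,0}, oc = {0,0,0};
          for (int c = 0; c < ni; ++c) {
            ic.x += cp[in_idx[c]].x / ni; ic.y += cp[in_idx[c]].y / ni;
            ic.z += cp[in_idx[c]].z / ni;
          }
          for (int c = 0; c < no; ++c) {
            oc.x += cp[out_idx[c]].x / no; oc.y += cp[out_idx[c]].y / no;
            oc.z += cp[out_idx[c]].z / no;
          }
          if (ni == 1) {
            V3 a = iso_vertex(cp[in_idx[0]], cp[out_idx[0]],
                              cv[in_idx[0]], cv[out_idx[0]], iso);
            V3 b = iso_vertex(cp[in_idx[0]], cp[out_idx[1]],
                              cv[in_idx[0]], cv[out_idx[1]], iso);
            V3 c = iso_vertex(cp[in_idx[0]], cp[out_idx[2]],
                              cv[in_idx[0]], cv[out_idx[2]], iso);
            add_tri(a, b, c, ic, oc, area, vol6);
          } else if (ni == 3) {
            V3 a = iso_vertex(cp[in_idx[0]], cp[out_idx[0]],
                              cv[in_idx[0]], cv[out_idx[0]], iso);
            V3 b = iso_vertex(cp[in_idx[1]], cp[out_idx[0]],
                              cv[in_idx[1]], cv[out_idx[0]], iso);
            V3 c = iso_vertex(cp[in_idx[2]], cp[out_idx[0]],
                              cv[in_idx[2]], cv[out_idx[0]], iso);
            add_tri(a, b, c, ic, oc, area, vol6);
          } else {
            // two in, two out: quad v(A1,B1)-v(A1,B2)-v(A2,B2)-v(A2,B1)
            V3 q1 = iso_vertex(cp[in_idx[0]], cp[out_idx[0]],
                               cv[in_idx[0]], cv[out_idx[0]], iso);
            V3 q2 = iso_vertex(cp[in_idx[0]], cp[out_idx[1]],
                               cv[in_idx[0]], cv[out_idx[1]], iso);
            V3 q3 = iso_vertex(cp[in_idx[1]], cp[out_idx[1]],
                               cv[in_idx[1]], cv[out_idx[1]], iso);
            V3 q4 = iso_vertex(cp[in_idx[1]], cp[out_idx[0]],
                               cv[in_idx[1]], cv[out_idx[0]], iso);
            add_tri(q1, q2, q3, ic, oc, area, vol6);
            add_tri(q1, q3, q4, ic, oc, area, vol6);
          }
        }
      }
  return List::create(_["surface_area"] = area,
                      _["mesh_volume"] = std::fabs(vol6) / 6.0);
}

// Maximum pairwise diameters over surface voxels: full 3D plus the three
// in-plane maxima (pairs sharing a slice index along the fixed axis).
// coords: m x 3 physical coordinates; idx: m x 3 integer grid indices.
// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix coords, IntegerMatrix idx) {
  const int m = coords.nrow();
  double d3 = 0, dz = 0, dy = 0, dx = 0;   // 3D, same-z (xy), same-y (xz), same-x (yz)
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      double ddx = coords(a,0) - coords(b,0);
      double ddy = coords(a,1) - coords(b,1);
      double ddz = coords(a,2) - coords(b,2);
      double q = ddx*ddx + ddy*ddy + ddz*ddz;
      if (q > d3) d3 = q;
      if (idx(a,2) == idx(b,2)) { double q2 = ddx*ddx + ddy*ddy; if (q2 > dz) dz = q2; }
      if (idx(a,1) == idx(b,1)) { double q2 = ddx*ddx + ddz*ddz; if (q2 > dy) dy = q2; }
      if (idx(a,0) == idx(b,0)) { double q2 = ddy*ddy + ddz*ddz; if (q2 > dx) dx = q2; }
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dz), std::sqrt(dy),
                               std::sqrt(dx));
}
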