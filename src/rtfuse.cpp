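// Numerical core: interpolation, median filtering, B-spline FFD evaluation,
// joint histogramming and the local-support NMI gradient used by the FFD
// optimizer. All voxel indices here are 0-based continuous indices with the
// convention "index i <-> voxel centre". World units are mm throughout.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double getvox(const double *v, const int *d, int x, int y, int z) {
  return v[x + (size_t)d[0] * (y + (size_t)d[1] * z)];
}

// Uniform cubic B-spline basis B_0..B_3 at fraction t in [0,1).
static inline void bspline_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Catmull-Rom (interpolating C1 cubic) weights at fraction t.
static inline void catmullrom_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline double lanczos3(double x) {
  if (x == 0.0) return 1.0;
  double ax = std::fabs(x);
  if (ax >= 3.0) return 0.0;
  double px = M_PI * x;
  return 3.0 * std::sin(px) * std::sin(px / 3.0) / (px * px);
}

// Trilinear sample at continuous index (cx,cy,cz); pad outside the closed
// sample hull [0, d-1] per axis.
static inline double trilinear(const double *v, const int *d,
                               double cx, double cy, double cz, double pad) {
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
      cx > d[0] - 1.0 || cy > d[1] - 1.0 || cz > d[2] - 1.0)
    return pad;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  if (x0 > d[0] - 2) x0 = d[0] - 2;
  if (y0 > d[1] - 2) y0 = d[1] - 2;
  if (z0 > d[2] - 2) z0 = d[2] - 2;
  if (d[0] == 1) x0 = 0;
  if (d[1] == 1) y0 = 0;
  if (d[2] == 1) z0 = 0;
  double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  int x1 = clampi(x0 + 1, 0, d[0] - 1);
  int y1 = clampi(y0 + 1, 0, d[1] - 1);
  int z1 = clampi(z0 + 1, 0, d[2] - 1);
  double c000 = getvox(v, d, x0, y0, z0), c100 = getvox(v, d, x1, y0, z0);
  double c010 = getvox(v, d, x0, y1, z0), c110 = getvox(v, d, x1, y1, z0);
  double c001 = getvox(v, d, x0, y0, z1), c101 = getvox(v, d, x1, y0, z1);
  double c011 = getvox(v, d, x0, y1, z1), c111 = getvox(v, d, x1, y1, z1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Generic 4-tap separable kernel sample (Catmull-Rom / B-spline kernel).
static inline double cubic_sample(const double *v, const int *d,
                                  double cx, double cy, double cz, double pad,
                                  bool bspline) {
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
      cx > d[0] - 1.0 || cy > d[1] - 1.0 || cz > d[2] - 1.0)
    return pad;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  double wx[4], wy[4], wz[4];
  if (bspline) {
    bspline_w(cx - x0, wx); bspline_w(cy - y0, wy); bspline_w(cz - z0, wz);
  } else {
    catmullrom_w(cx - x0, wx); catmullrom_w(cy - y0, wy); catmullrom_w(cz - z0, wz);
  }
  double acc = 0.0;
  for (int k = 0; k < 4; k++) {
    int zz = clampi(z0 - 1 + k, 0, d[2] - 1);
    for (int j = 0; j < 4; j++) {
      int yy = clampi(y0 - 1 + j, 0, d[1] - 1);
      double wyz = wy[j] * wz[k];
      for (int i = 0; i < 4; i++) {
        int xx = clampi(x0 - 1 + i, 0, d[0] - 1);
        acc += wx[i] * wyz * getvox(v, d, xx, yy, zz);
      }
    }
  }
  return acc;
}

static inline double sinc_sample(const double *v, const int *d,
                                 double cx, double cy, double cz, double pad) {
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
      cx > d[0] - 1.0 || cy > d[1] - 1.0 || cz > d[2] - 1.0)
    return pad;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  double wx[6], wy[6], wz[6], sx = 0, sy = 0, sz = 0;
  for (int i = 0; i < 6; i++) {
    wx[i] = lanczos3(cx - (x0 - 2 + i)); sx += wx[i];
    wy[i] = lanczos3(cy - (y0 - 2 + i)); sy += wy[i];
    wz[i] = lanczos3(cz - (z0 - 2 + i)); sz += wz[i];
  }
  double acc = 0.0;
  for (int k = 0; k < 6; k++) {
    int zz = clampi(z0 - 2 + k, 0, d[2] - 1);
    for (int j = 0; j < 6; j++) {
      int yy = clampi(y0 - 2 + j, 0, d[1] - 1);
      double wyz = wy[j] * wz[k];
      for (int i = 0; i < 6; i++) {
        int xx = clampi(x0 - 2 + i, 0, d[0] - 1);
        acc += wx[i] * wyz * getvox(v, d, xx, yy, zz);
      }
    }
  }
  return acc / (sx * sy * sz);
}

// method: 0 nearest, 1 linear, 2 c1spline (Catmull-Rom), 3 cubic B-spline
// kernel, 4 Lanczos-3 windowed sinc. idx is N x 3 of continuous 0-based
// voxel indices.
// [[Rcpp::export]]
NumericVector c_interp(NumericVector vol, IntegerVector dim, NumericMatrix idx,
                       int method, double pad) {
  int n = idx.nrow();
  const double *v = REAL(vol);
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(n);
  for (int p = 0; p < n; p++) {
    double cx = idx(p, 0), cy = idx(p, 1), cz = idx(p, 2);
    double val;
    if (!R_finite(cx) || !R_finite(cy) || !R_finite(cz)) { out[p] = pad; continue; }
    switch (method) {
    case 0: {
      if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
          cx > d[0] - 1.0 || cy > d[1] - 1.0 || cz > d[2] - 1.0) { val = pad; break; }
      int x = clampi((int)std::floor(cx + 0.5), 0, d[0] - 1);
      int y = clampi((int)std::floor(cy + 0.5), 0, d[1] - 1);
      int z = clampi((int)std::floor(cz + 0.5), 0, d[2] - 1);
      val = getvox(v, d, x, y, z);
      break;
    }
    case 1: val = trilinear(v, d, cx, cy, cz, pad); break;
    case 2: val = cubic_sample(v, d, cx, cy, cz, pad, false); break;
    case 3: val = cubic_sample(v, d, cx, cy, cz, pad, true); break;
    case 4: val = sinc_sample(v, d, cx, cy, cz, pad); break;
    default: stop("unknown interpolation method code");
    }
    out[p] = val;
  }
  return out;
}

// Median filter with edge replication; radius r per axis (voxels).
// [[Rcpp::export]]
NumericVector c_median_filter(NumericVector vol, IntegerVector dim, IntegerVector r) {
  int d[3] = {dim[0], dim[1], dim[2]};
  const double *v = REAL(vol);
  NumericVector out((size_t)d[0] * d[1] * d[2]);
  int nn = (2 * r[0] + 1) * (2 * r[1] + 1) * (2 * r[2] + 1);
  std::vector<double> buf(nn);
  size_t o = 0;
  for (int z = 0; z < d[2]; z++)
    for (int y = 0; y < d[1]; y++)
      for (int x = 0; x < d[0]; x++, o++) {
        int m = 0;
        for (int dz = -r[2]; dz <= r[2]; dz++) {
          int zz = clampi(z + dz, 0, d[2] - 1);
          for (int dy = -r[1]; dy <= r[1]; dy++) {
            int yy = clampi(y + dy, 0, d[1] - 1);
            for (int dx = -r[0]; dx <= r[0]; dx++)
              buf[m++] = getvox(v, d, clampi(x + dx, 0, d[0] - 1), yy, zz);
          }
        }
        std::nth_element(buf.begin(), buf.begin() + nn / 2, buf.begin() + nn);
        out[o] = buf[nn / 2];
      }
  return out;
}

// Separable Gaussian smoothing (edge replication), sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector c_gauss_smooth(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int d[3] = {dim[0], dim[1], dim[2]};
  size_t n = (size_t)d[0] * d[1] * d[2];
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; i++) { k[i + rad] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + rad]; }
    for (int i = 0; i < 2 * rad + 1; i++) k[i] /= ksum;
    for (int z = 0; z < d[2]; z++)
      for (int y = 0; y < d[1]; y++)
        for (int x = 0; x < d[0]; x++) {
          double acc = 0.0;
          for (int i = -rad; i <= rad; i++) {
            int xx = x, yy = y, zz = z;
            if (ax == 0) xx = clampi(x + i, 0, d[0] - 1);
            else if (ax == 1) yy = clampi(y + i, 0, d[1] - 1);
            else zz = clampi(z + i, 0, d[2] - 1);
            acc += k[i + rad] * a[xx + (size_t)d[0] * (yy + (size_t)d[1] * zz)];
          }
          b[x + (size_t)d[0] * (y + (size_t)d[1] * z)] = acc;
        }
    a.swap(b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// FFD displacement at world points. coef has layout (nx,ny,nz,3), x fastest.
// Points without a full 4x4x4 control neighbourhood get zero displacement.
// strict+roi reproduces the literal piecewise form: zero outside the ROI box.
// [[Rcpp::export]]
NumericMatrix c_ffd_disp(NumericVector coef, IntegerVector shape,
                         NumericVector origin, NumericVector spacing,
                         NumericMatrix pts, bool strict, bool has_roi,
                         NumericVector roi_lo, NumericVector roi_hi) {
  int n = pts.nrow();
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t nc = (size_t)nx * ny * nz;
  const double *cf = REAL(coef);
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; p++) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    if (strict && has_roi) {
      if (px < roi_lo[0] || px > roi_hi[0] || py < roi_lo[1] || py > roi_hi[1] ||
          pz < roi_lo[2] || pz > roi_hi[2])
        continue;  // literal piecewise case: identity outside the ROI
    }
    double g[3] = {(px - origin[0]) / spacing[0],
                   (py - origin[1]) / spacing[1],
                   (pz - origin[2]) / spacing[2]};
    int f[3];
    bool ok = true;
    for (int a = 0; a < 3; a++) {
      f[a] = (int)std::floor(g[a]);
      if (f[a] - 1 < 0 || f[a] + 2 > shape[a] - 1) { ok = false; break; }
    }
    if (!ok) continue;
    double wx[4], wy[4], wz[4];
    bspline_w(g[0] - f[0], wx);
    bspline_w(g[1] - f[1], wy);
    bspline_w(g[2] - f[2], wz);
    double acc[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < 4; k++) {
      int ck = f[2] - 1 + k;
      for (int j = 0; j < 4; j++) {
        int cj = f[1] - 1 + j;
        double wyz = wy[j] * wz[k];
        size_t base = (size_t)nx * (cj + (size_t)ny * ck);
        for (int i = 0; i < 4; i++) {
          double w = wx[i] * wyz;
          size_t ci = base + (f[0] - 1 + i);
          acc[0] += w * cf[ci];
          acc[1] += w * cf[ci + nc];
          acc[2] += w * cf[ci + 2 * nc];
        }
      }
    }
    out(p, 0) = acc[0]; out(p, 1) = acc[1]; out(p, 2) = acc[2];
  }
  return out;
}

static inline int bin_of(double x, double lo, double w, int bins) {
  int b = (int)std::floor((x - lo) / w);
  return clampi(b, 0, bins - 1);
}

// Equal-width hard binning; non-finite -> -1.
// [[Rcpp::export]]
IntegerVector c_bin_values(NumericVector x, double lo, double w, int bins) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = R_finite(x[i]) ? bin_of(x[i], lo, w, bins) : -1;
  return out;
}

// Joint histogram from precomputed bin indices (-1 excluded pairwise).
// [[Rcpp::export]]
NumericMatrix c_hist_from_bins(IntegerVector ba, IntegerVector bb, int bins) {
  NumericMatrix h(bins, bins);
  int n = ba.size();
  for (int i = 0; i < n; i++) {
    if (ba[i] < 0 || bb[i] < 0) continue;
    h(ba[i], bb[i]) += 1.0;
  }
  return h;
}

static inline double xlogx(double c) { return c > 0.0 ? c * std::log(c) : 0.0; }

// NMI finite-difference gradient over FFD coefficients using local support:
// perturbing one control point only moves samples of voxels within two
// control spacings, so only their joint-histogram contributions are updated.
// Entropy sums are maintained incrementally; the result equals a full
// recomputation of the central difference.
//
// base_idx: N x 3 continuous source-voxel indices at the current transform.
// tgt_bin/base_bin: per-reference-voxel bins (target fixed, source at base).
// g0/gd: lattice coordinate of ref voxel (ix,iy,iz) axis a = g0[a]+i*gd[a].
// step_idx: 3x3; column a = d(source index)/d(world displacement axis a).
// [[Rcpp::export]]
NumericVector c_nmi_grad_ffd(NumericVector src, IntegerVector sdim,
                             IntegerVector rdim, NumericMatrix base_idx,
                             IntegerVector base_bin, IntegerVector tgt_bin,
                             IntegerVector shape, LogicalVector free_mask,
                             NumericVector g0, NumericVector gd,
                             NumericMatrix step_idx, int bins,
                             double b_lo, double b_w, double h, double pad) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t nc = (size_t)nx * ny * nz;
  const double *sv = REAL(src);
  int sd[3] = {sdim[0], sdim[1], sdim[2]};
  int rd[3] = {rdim[0], rdim[1], rdim[2]};

  // base joint + marginal counts and entropy sums
  std::vector<double> joint((size_t)bins * bins, 0.0), msrc(bins, 0.0), mtgt(bins, 0.0);
  size_t nvox = (size_t)rd[0] * rd[1] * rd[2];
  double ntot = 0.0;
  for (size_t i = 0; i < nvox; i++) {
    if (tgt_bin[i] < 0 || base_bin[i] < 0) continue;
    joint[tgt_bin[i] + (size_t)bins * base_bin[i]] += 1.0;
    msrc[base_bin[i]] += 1.0;
    mtgt[tgt_bin[i]] += 1.0;
    ntot += 1.0;
  }
  if (ntot <= 0) stop("no valid voxels for NMI gradient");
  double Sj = 0.0, Sb = 0.0, Sa = 0.0;
  for (size_t i = 0; i < (size_t)bins * bins; i++) Sj += xlogx(joint[i]);
  for (int i = 0; i < bins; i++) { Sb += xlogx(msrc[i]); Sa += xlogx(mtgt[i]); }
  double logn = std::log(ntot);
  double Ha = logn - Sa / ntot;

  NumericVector grad(nc * 3);

  // per-axis tables: floor of the lattice coordinate and the four basis
  // weights at every reference voxel index (computed once, reused for every
  // control point)
  std::vector<int> ftab[3];
  std::vector<double> wtab[3];
  for (int a = 0; a < 3; a++) {
    if (gd[a] <= 0) stop("lattice coordinate step must be positive");
    ftab[a].resize(rd[a]);
    wtab[a].resize((size_t)rd[a] * 4);
    for (int i = 0; i < rd[a]; i++) {
      double g = g0[a] + i * gd[a];
      int f = (int)std::floor(g);
      ftab[a][i] = f;
      bspline_w(g - f, &wtab[a][(size_t)i * 4]);
    }
  }
  const double *bix = REAL(base_idx);           // column-major, 3 columns
  const double *biy = bix + nvox, *biz = bix + 2 * nvox;
  const int *tb = INTEGER(tgt_bin), *bb = INTEGER(base_bin);

  // support buffer per control point, reused for all 3 axes x 2 signs
  std::vector<size_t> sup_v; std::vector<double> sup_w;
  sup_v.reserve(8192); sup_w.reserve(8192);
  std::vector<int> chg_idx; chg_idx.reserve(4096);

  for (int ck = 0; ck < nz; ck++)
    for (int cj = 0; cj < ny; cj++)
      for (int ci = 0; ci < nx; ci++) {
        size_t clin = ci + (size_t)nx * (cj + (size_t)ny * ck);
        if (!free_mask[clin]) continue;
        int cc[3] = {ci, cj, ck};
        // voxel index window where this control point has support
        int lo[3], hi[3];
        bool empty = false;
        for (int a = 0; a < 3; a++) {
          double gmin = std::max((double)(cc[a] - 2), 1.0);
          double gmax = std::min((double)(cc[a] + 2), (double)(shape[a] - 2));
          lo[a] = std::max((int)std::ceil((gmin - g0[a]) / gd[a] - 1e-12), 0);
          hi[a] = std::min((int)std::floor((gmax - g0[a]) / gd[a] - 1e-12),
                           rd[a] - 1);
          if (lo[a] > hi[a]) { empty = true; break; }
        }
        if (empty) continue;
        // gather support voxels and their tensor weights once
        sup_v.clear(); sup_w.clear();
        for (int iz = lo[2]; iz <= hi[2]; iz++) {
          int fz = ftab[2][iz];
          if (fz < 1 || fz > shape[2] - 3) continue;  // no full neighbourhood
          int lz = ck - (fz - 1);
          if (lz < 0 || lz > 3) continue;
          double wz = wtab[2][(size_t)iz * 4 + lz];
          for (int iy = lo[1]; iy <= hi[1]; iy++) {
            int fy = ftab[1][iy];
            if (fy < 1 || fy > shape[1] - 3) continue;
            int ly = cj - (fy - 1);
            if (ly < 0 || ly > 3) continue;
            double wyz = wtab[1][(size_t)iy * 4 + ly] * wz;
            if (wyz == 0.0) continue;
            size_t rowbase = (size_t)rd[0] * (iy + (size_t)rd[1] * iz);
            for (int ix = lo[0]; ix <= hi[0]; ix++) {
              int fx = ftab[0][ix];
              if (fx < 1 || fx > shape[0] - 3) continue;
              int lx = ci - (fx - 1);
              if (lx < 0 || lx > 3) continue;
              size_t vlin = rowbase + ix;
              if (tb[vlin] < 0 || bb[vlin] < 0) continue;
              double w = wtab[0][(size_t)ix * 4 + lx] * wyz;
              if (w == 0.0) continue;
              sup_v.push_back(vlin);
              sup_w.push_back(w);
            }
          }
        }
        if (sup_v.empty()) continue;
        for (int a = 0; a < 3; a++) {
          double dix = step_idx(0, a), diy = step_idx(1, a), diz = step_idx(2, a);
          double nmi_pm[2];
          for (int s = 0; s < 2; s++) {
            double sh = (s == 0 ? h : -h);
            double Sj2 = Sj, Sb2 = Sb;
            chg_idx.clear();
            for (size_t q = 0; q < sup_v.size(); q++) {
              size_t vlin = sup_v[q];
              double del = sh * sup_w[q];
              double val = trilinear(sv, sd, bix[vlin] + del * dix,
                                     biy[vlin] + del * diy,
                                     biz[vlin] + del * diz, pad);
              int bo = bb[vlin];
              int bn = R_finite(val) ? bin_of(val, b_lo, b_w, bins) : bo;
              if (bn == bo) continue;
              int bt = tb[vlin];
              size_t jo = bt + (size_t)bins * bo, jn = bt + (size_t)bins * bn;
              Sj2 += xlogx(joint[jo] - 1.0) - xlogx(joint[jo]);
              Sj2 += xlogx(joint[jn] + 1.0) - xlogx(joint[jn]);
              joint[jo] -= 1.0; joint[jn] += 1.0;
              Sb2 += xlogx(msrc[bo] - 1.0) - xlogx(msrc[bo]);
              Sb2 += xlogx(msrc[bn] + 1.0) - xlogx(msrc[bn]);
              msrc[bo] -= 1.0; msrc[bn] += 1.0;
              chg_idx.push_back((int)jo);
              chg_idx.push_back((int)jn);
            }
            double Hb = logn - Sb2 / ntot;
            double Hab = logn - Sj2 / ntot;
            nmi_pm[s] = (Ha + Hb) / Hab;
            for (int q = (int)chg_idx.size() - 2; q >= 0; q -= 2) {
              size_t jo = chg_idx[q], jn = chg_idx[q + 1];
              joint[jo] += 1.0; joint[jn] -= 1.0;
              msrc[jo / bins] += 1.0; msrc[jn / bins] -= 1.0;
            }
          }
          grad[clin + a * nc] = (nmi_pm[0] - nmi_pm[1]) / (2.0 * h);
        }
      }
  return grad;
}

// Entropy report from a joint histogram: H(A), H(B), H(A,B) in nats.
// [[Rcpp::export]]
NumericVector c_hist_entropies(NumericMatrix joint) {
  int br = joint.nrow(), bc = joint.ncol();
  double n = 0.0;
  std::vector<double> ma(br, 0.0), mb(bc, 0.0);
  for (int j = 0; j < bc; j++)
    for (int i = 0; i < br; i++) {
      double c = joint(i, j);
      n += c; ma[i] += c; mb[j] += c;
    }
  if (n <= 0) return NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  double Sa = 0, Sb = 0, Sj = 0;
  for (int i = 0; i < br; i++) Sa += xlogx(ma[i]);
  for (int j = 0; j < bc; j++) Sb += xlogx(mb[j]);
  for (int j = 0; j < bc; j++)
    for (int i = 0; i < br; i++) Sj += xlogx(joint(i, j));
  double logn = std::log(n);
  return NumericVector::create(logn - Sa / n, logn - Sb / n, logn - Sj / n);
}
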