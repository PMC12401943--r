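#include <Rcpp.h>
#include <cmath>
#include <array>
#include <vector>
#include <utility>
using namespace Rcpp;

// Analytic primitives are encoded as rows of a numeric matrix:
//   col 0: kind (1 ellipsoid, 2 elliptic cylinder (z-aligned), 3 circular rod,
//          4 cone frustum)
//   cols 1-3: center (mm)
//   cols 4-6: shape parameters p1,p2,p3
//     ellipsoid:        semi-axes a,b,c (axis-aligned)
//     elliptic cyl:     semi-axes a,b and half-length in z
//     circular rod:     radius, half-length, unused
//     cone frustum:     base radius, apex radius, half-length along axis
//   cols 7-9: unit axis direction (rod/frustum; base -> apex)
//   col 10: delta_mu (mm^-1); the water background carries mu_water here
static const int PKIND = 0, PCX = 1, PP1 = 4, PUX = 7, PDMU = 10;

struct Seg { double a, b; };

// chord length of {A t^2 + B t + C <= 0} within [lo, hi]
static inline double quad_chord(double A, double B, double C,
                                double lo, double hi) {
  if (hi <= lo) return 0.0;
  const double tiny = 1e-14;
  if (std::fabs(A) < tiny) {
    if (std::fabs(B) < tiny) return (C <= 0.0) ? (hi - lo) : 0.0;
    double t0 = -C / B;
    if (B > 0.0) { double h = std::min(hi, t0); return std::max(0.0, h - lo); }
    double l = std::max(lo, t0); return std::max(0.0, hi - l);
  }
  double disc = B * B - 4.0 * A * C;
  if (A > 0.0) {
    if (disc <= 0.0) return 0.0;
    double s = std::sqrt(disc);
    double t1 = (-B - s) / (2.0 * A), t2 = (-B + s) / (2.0 * A);
    double l = std::max(lo, t1), h = std::min(hi, t2);
    return std::max(0.0, h - l);
  }
  // A < 0: region is outside the roots
  if (disc <= 0.0) return hi - lo;
  double s = std::sqrt(disc);
  double r1 = (-B + s) / (2.0 * A), r2 = (-B - s) / (2.0 * A); // r1 < r2
  double len = 0.0;
  len += std::max(0.0, std::min(hi, r1) - lo);
  len += std::max(0.0, hi - std::max(lo, r2));
  return len;
}

// clip [lo,hi] by slab |q + t d| <= h; returns false if empty
static inline bool slab_clip(double q, double d, double h,
                             double &lo, double &hi) {
  const double tiny = 1e-14;
  if (std::fabs(d) < tiny) return std::fabs(q) <= h;
  double t1 = (-h - q) / d, t2 = (h - q) / d;
  if (t1 > t2) std::swap(t1, t2);
  lo = std::max(lo, t1); hi = std::min(hi, t2);
  return hi > lo;
}

static double primitive_chord(const double *pr, const double *o,
                              const double *d, double tmin, double tmax) {
  int kind = (int)pr[PKIND];
  double cx = pr[PCX], cy = pr[PCX + 1], cz = pr[PCX + 2];
  double p1 = pr[PP1], p2 = pr[PP1 + 1], p3 = pr[PP1 + 2];
  double qx = o[0] - cx, qy = o[1] - cy, qz = o[2] - cz;
  double lo = tmin, hi = tmax;
  if (kind == 1) { // ellipsoid
    double ux = qx / p1, uy = qy / p2, uz = qz / p3;
    double vx = d[0] / p1, vy = d[1] / p2, vz = d[2] / p3;
    double A = vx * vx + vy * vy + vz * vz;
    double B = 2.0 * (ux * vx + uy * vy + uz * vz);
    double C = ux * ux + uy * uy + uz * uz - 1.0;
    return quad_chord(A, B, C, lo, hi);
  }
  if (kind == 2) { // z-aligned elliptic cylinder, half-length p3
    if (!slab_clip(qz, d[2], p3, lo, hi)) return 0.0;
    double ux = qx / p1, uy = qy / p2, vx = d[0] / p1, vy = d[1] / p2;
    double A = vx * vx + vy * vy;
    double B = 2.0 * (ux * vx + uy * vy);
    double C = ux * ux + uy * uy - 1.0;
    return quad_chord(A, B, C, lo, hi);
  }
  // rod / frustum: local frame along unit axis u
  double ux = pr[PUX], uy = pr[PUX + 1], uz = pr[PUX + 2];
  double qa = qx * ux + qy * uy + qz * uz;       // axial components
  double da = d[0] * ux + d[1] * uy + d[2] * uz;
  double qpx = qx - qa * ux, qpy = qy - qa * uy, qpz = qz - qa * uz;
  double dpx = d[0] - da * ux, dpy = d[1] - da * uy, dpz = d[2] - da * uz;
  double qq = qpx * qpx + qpy * qpy + qpz * qpz;
  double qd = qpx * dpx + qpy * dpy + qpz * dpz;
  double dd = dpx * dpx + dpy * dpy + dpz * dpz;
  if (kind == 3) { // circular rod: radius p1, half-length p2
    if (!slab_clip(qa, da, p2, lo, hi)) return 0.0;
    return quad_chord(dd, 2.0 * qd, qq - p1 * p1, lo, hi);
  }
  // kind == 4: cone frustum, radius r(z') = rm + s z', z' in [-h, h]
  double h = p3, rm = 0.5 * (p1 + p2), sl = (p2 - p1) / (2.0 * h);
  if (!slab_clip(qa, da, h, lo, hi)) return 0.0;
  double A = dd - sl * sl * da * da;
  double B = 2.0 * (qd - sl * sl * qa * da - rm * sl * da);
  double C = qq - rm * rm - 2.0 * rm * sl * qa - sl * sl * qa * qa;
  return quad_chord(A, B, C, lo, hi);
}

// [[Rcpp::export]]
NumericVector cpp_line_integrals(NumericMatrix prims, NumericMatrix origins,
                                 NumericMatrix dirs, NumericVector tmin,
                                 NumericVector tmax) {
  int nray = origins.nrow(), nprim = prims.nrow();
  NumericVector out(nray);
  std::vector<double> P(nprim * 11);
  for (int j = 0; j < nprim; ++j)
    for (int c = 0; c < 11; ++c) P[j * 11 + c] = prims(j, c);
  for (int i = 0; i < nray; ++i) {
    double o[3] = { origins(i, 0), origins(i, 1), origins(i, 2) };
    double d[3] = { dirs(i, 0), dirs(i, 1), dirs(i, 2) };
    double lo = tmin[i % tmin.size()], hi = tmax[i % tmax.size()];
    double acc = 0.0;
    for (int j = 0; j < nprim; ++j)
      acc += P[j * 11 + PDMU] * primitive_chord(&P[j * 11], o, d, lo, hi);
    out[i] = acc;
  }
  return out;
}

static inline bool point_inside(const double *pr, double x, double y,
                                double z) {
  int kind = (int)pr[PKIND];
  double qx = x - pr[PCX], qy = y - pr[PCX + 1], qz = z - pr[PCX + 2];
  double p1 = pr[PP1], p2 = pr[PP1 + 1], p3 = pr[PP1 + 2];
  if (kind == 1) {
    double s = qx * qx / (p1 * p1) + qy * qy / (p2 * p2) + qz * qz / (p3 * p3);
    return s <= 1.0;
  }
  if (kind == 2) {
    if (std::fabs(qz) > p3) return false;
    return qx * qx / (p1 * p1) + qy * qy / (p2 * p2) <= 1.0;
  }
  double ux = pr[PUX], uy = pr[PUX + 1], uz = pr[PUX + 2];
  double qa = qx * ux + qy * uy + qz * uz;
  double pp = qx * qx + qy * qy + qz * qz - qa * qa;
  if (kind == 3) return std::fabs(qa) <= p2 && pp <= p1 * p1;
  double h = p3, rm = 0.5 * (p1 + p2), sl = (p2 - p1) / (2.0 * h);
  if (std::fabs(qa) > h) return false;
  double r = rm + sl * qa;
  return pp <= r * r;
}

// total mu (mm^-1) at each point (background included)
// [[Rcpp::export]]
NumericVector cpp_point_mu(NumericMatrix prims, NumericMatrix pts) {
  int np = pts.nrow(), nprim = prims.nrow();
  NumericVector out(np);
  std::vector<double> P(nprim * 11);
  for (int j = 0; j < nprim; ++j)
    for (int c = 0; c < 11; ++c) P[j * 11 + c] = prims(j, c);
  for (int i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2), acc = 0.0;
    for (int j = 0; j < nprim; ++j)
      if (point_inside(&P[j * 11], x, y, z)) acc += P[j * 11 + PDMU];
    out[i] = acc;
  }
  return out;
}

// Forward projection of one schedule. Source at gantry angle beta sits at
// R(-sin b, cos b) in-plane with z = z_table + spot_z; the curved detector is
// a cylinder of radius R+D around the source xy-position, rows flat in z and
// centred at z_table. gamma increases along e = -(cos b, sin b, 0) so that
// conjugate rays satisfy (beta, gamma) <-> (beta + pi - 2 gamma, -gamma).
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericMatrix prims, double R, double D,
                                  NumericVector beta, NumericVector spot_z,
                                  NumericVector z_table, int nrow_det,
                                  int nchan, double dgamma,
                                  double row_pitch_phys) {
  int nview = beta.size(), nprim = prims.nrow();
  NumericVector out((R_xlen_t)nview * nrow_det * nchan);
  std::vector<double> P(nprim * 11);
  for (int j = 0; j < nprim; ++j)
    for (int c = 0; c < 11; ++c) P[j * 11 + c] = prims(j, c);
  double c0 = 0.5 * (nchan - 1), r0 = 0.5 * (nrow_det - 1);
  double RD = R + D;
  R_xlen_t idx = 0;
  for (int v = 0; v < nview; ++v) {
    double sb = std::sin(beta[v]), cb = std::cos(beta[v]);
    double Sx = -R * sb, Sy = R * cb, Sz = z_table[v] + spot_z[v];
    double u0x = sb, u0y = -cb;      // unit source -> iso
    double ex = -cb, ey = -sb;       // gamma direction
    for (int r = 0; r < nrow_det; ++r) {
      double Ez = z_table[v] + (r - r0) * row_pitch_phys;
      for (int c = 0; c < nchan; ++c, ++idx) {
        double g = (c - c0) * dgamma;
        double cg = std::cos(g), sg = std::sin(g);
        double Ex = Sx + RD * (cg * u0x + sg * ex);
        double Ey = Sy + RD * (cg * u0y + sg * ey);
        double dx = Ex - Sx, dy = Ey - Sy, dz = Ez - Sz;
        double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
        double d[3] = { dx / nrm, dy / nrm, dz / nrm };
        double o[3] = { Sx, Sy, Sz };
        double acc = 0.0;
        for (int j = 0; j < nprim; ++j)
          acc += P[j * 11 + PDMU] *
                 primitive_chord(&P[j * 11], o, d, 0.0, nrm);
        out[idx] = acc;
      }
    }
  }
  return out;
}

// Parker short-scan weight; beta measured from the start of the short scan
// spanning [0, pi + 2 gm]. Conjugate pairs (b, g) and (b + pi - 2 g, -g)
// sum to 1.
static inline double parker_w(double b, double g, double gm) {
  if (b < 0.0 || b > M_PI + 2.0 * gm) return 0.0;
  double pi4 = M_PI / 4.0;
  if (b < 2.0 * (gm + g)) {
    double s = std::sin(pi4 * b / (gm + g));
    return s * s;
  }
  if (b <= M_PI + 2.0 * g) return 1.0;
  double s = std::sin(pi4 * (M_PI + 2.0 * gm - b) / (gm - g));
  return s * s;
}

// [[Rcpp::export]]
NumericVector cpp_parker_weights(NumericVector beta, NumericVector gamma,
                                 double gamma_m) {
  int n = beta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = parker_w(beta[i], gamma[i], gamma_m);
  return out;
}

// ---------------------------------------------------------------------------
// Weighted cone-beam backprojection, pixel-wise weighting stage.
//
// All in-plane redundancy weighting is applied to the projections BEFORE
// filtering (exact): Parker weights for axial short scans, the 1/2
// full-scan factor for axial full scans, and per-slice generalized
// redundancy weights (conjugate- and spot-normalized, cone-tapered) for
// helical scans. The backprojector applies only the weight that must be
// pixel-wise: for axial multi-spot scans, the cone-angle-dependent blend
// cos^k(kappa_spot) normalized over the spots whose beam covers the voxel
// at the same gantry angle. Rays beyond the detector's z-extent use
// nearest-row extrapolation; for multi-spot scans a pose is extrapolated
// only when no spot genuinely covers it, from the spot whose detector edge
// is nearest. The voxel value is 2 * dbeta_per_spot * sum(w q / L^2)
// (factor applied by the caller).
// ---------------------------------------------------------------------------

struct BPPar {
  double R, D, rpp;              // distances, physical row pitch
  int nrow;
  std::vector<double> spots;     // spot z-offsets
  double zt_ref;                 // axial table position
  double cone_k;
};

struct MeasW { bool ok; double w; };

// cone-weighted availability of the measurement of voxel (x,y,z) by spot si
// at gantry angle b; need_rows = false skips the detector-row coverage
// check (used by the extrapolation fallback)
static MeasW measurement_weight(const BPPar &bp, double x, double y, double z,
                                double b, int si, bool need_rows) {
  MeasW m = { false, 0.0 };
  double zt = bp.zt_ref;
  double sb = std::sin(b), cb = std::cos(b);
  double Sx = -bp.R * sb, Sy = bp.R * cb;
  double Sz = zt + bp.spots[si];
  double wx = x - Sx, wy = y - Sy;
  double L2 = wx * wx + wy * wy, L = std::sqrt(L2);
  if (need_rows) {
    double zdet = Sz + (z - Sz) * (bp.R + bp.D) / L;
    double rf = (zdet - zt) / bp.rpp + 0.5 * (bp.nrow - 1);
    if (rf < 0.0 || rf > bp.nrow - 1) return m;
  }
  m.ok = true;
  m.w = 1.0;
  if (bp.cone_k > 0.0) {
    double dz = z - Sz;
    double ck = L / std::sqrt(L2 + dz * dz);
    m.w = (bp.cone_k == 2.0) ? ck * ck : std::pow(ck, bp.cone_k);
  }
  return m;
}

// blend normalization: sum of weights of all spots at the same pose
static double weight_set_total(const BPPar &bp, double x, double y, double z,
                               double b, bool need_rows) {
  double tot = 0.0;
  for (int s = 0; s < (int)bp.spots.size(); ++s) {
    MeasW m = measurement_weight(bp, x, y, z, b, s, need_rows);
    if (m.ok) tot += m.w;
  }
  return tot;
}

// row overshoot (in rows) of the pose for spot s; 0 if covered
static double row_overshoot(const BPPar &bp, double x, double y, double z,
                            double b, int s) {
  double sb = std::sin(b), cb = std::cos(b);
  double Sx = -bp.R * sb, Sy = bp.R * cb;
  double Sz = bp.zt_ref + bp.spots[s];
  double wx = x - Sx, wy = y - Sy;
  double L = std::sqrt(wx * wx + wy * wy);
  double zdet = Sz + (z - Sz) * (bp.R + bp.D) / L;
  double rf = (zdet - bp.zt_ref) / bp.rpp + 0.5 * (bp.nrow - 1);
  if (rf < 0.0) return -rf;
  if (rf > bp.nrow - 1) return rf - (bp.nrow - 1);
  return 0.0;
}

// q: filtered, redundancy-pre-weighted projections (nchan fastest, then
// rows, views); blend enables the axial multi-spot pixel-wise stage.
// Returns sum(w q / L^2) per voxel and the per-voxel sum of applied pixel
// weights.
// [[Rcpp::export]]
List cpp_backproject(NumericVector q, int nview, int nrow_det, int nchan,
                     NumericVector beta, IntegerVector spot_idx,
                     NumericVector z_table, NumericVector spots_z,
                     double R, double D, double dgamma,
                     double row_pitch_phys, int nx, int ny, double fov,
                     NumericVector slice_z, bool blend, double cone_k,
                     double zt_ref) {
  int nz = slice_z.size();
  NumericVector vol((R_xlen_t)nx * ny * nz), wsum((R_xlen_t)nx * ny * nz);
  BPPar bp;
  bp.R = R; bp.D = D; bp.rpp = row_pitch_phys; bp.nrow = nrow_det;
  bp.spots = std::vector<double>(spots_z.begin(), spots_z.end());
  bp.zt_ref = zt_ref; bp.cone_k = cone_k;
  double pix = fov / nx;
  double c0 = 0.5 * (nchan - 1), r0 = 0.5 * (nrow_det - 1);
  double RD = R + D;
  bool single = spots_z.size() == 1 || !blend;
  for (int iz = 0; iz < nz; ++iz) {
    double zv = slice_z[iz];
    for (int v = 0; v < nview; ++v) {
      double b = beta[v];
      int si = spot_idx[v];
      double sb = std::sin(b), cb = std::cos(b);
      double Sx = -R * sb, Sy = R * cb;
      double Sz = z_table[v] + spots_z[si];
      double u0x = sb, u0y = -cb, ex = -cb, ey = -sb;
      const double *qv = &q[(R_xlen_t)v * nrow_det * nchan];
      R_xlen_t base = (R_xlen_t)iz * nx * ny;
      for (int jy = 0; jy < ny; ++jy) {
        double y = (jy - 0.5 * (ny - 1)) * pix;
        for (int jx = 0; jx < nx; ++jx) {
          double x = (jx - 0.5 * (nx - 1)) * pix;
          double wx = x - Sx, wy = y - Sy;
          double L2 = wx * wx + wy * wy;
          double L = std::sqrt(L2);
          double g = std::atan2(wx * ex + wy * ey, wx * u0x + wy * u0y);
          double cf = g / dgamma + c0;
          if (cf < 0.0 || cf > nchan - 1) continue;
          double zdet = Sz + (zv - Sz) * RD / L;
          double rf = (zdet - z_table[v]) / row_pitch_phys + r0;
          bool genuine = (rf >= 0.0 && rf <= nrow_det - 1);
          double w = 1.0;
          if (single) {
            // nearest-row extrapolation at the collimation edge
            if (!genuine) rf = (rf < 0.0) ? 0.0 : nrow_det - 1;
          } else if (genuine) {
            MeasW self = measurement_weight(bp, x, y, zv, b, si, true);
            if (!self.ok) continue;
            w = self.w / weight_set_total(bp, x, y, zv, b, true);
          } else {
            // this spot's rows do not reach the voxel here: defer to a
            // spot that genuinely covers it, else extrapolate from the
            // spot whose detector edge is nearest
            if (weight_set_total(bp, x, y, zv, b, true) > 0.0) continue;
            double dself = row_overshoot(bp, x, y, zv, b, si);
            bool nearest = true;
            int ntie = 1;
            for (int s = 0; s < (int)bp.spots.size() && nearest; ++s) {
              if (s == si) continue;
              double ds = row_overshoot(bp, x, y, zv, b, s);
              if (ds < dself - 1e-9) nearest = false;
              else if (ds < dself + 1e-9) ++ntie; // split exact ties
            }
            if (!nearest) continue;
            w = 1.0 / ntie;
            rf = (rf < 0.0) ? 0.0 : nrow_det - 1;
          }
          int ci = (int)cf, ri = (int)rf;
          if (ci >= nchan - 1) ci = nchan - 2;
          if (ri >= nrow_det - 1) ri = nrow_det - 2;
          double fc = cf - ci, fr = rf - ri;
          const double *q0 = qv + (R_xlen_t)ri * nchan + ci;
          double val = (1.0 - fr) * ((1.0 - fc) * q0[0] + fc * q0[1]) +
                       fr * ((1.0 - fc) * q0[nchan] + fc * q0[nchan + 1]);
          R_xlen_t k = base + (R_xlen_t)jy * nx + jx;
          vol[k] += w * val / L2;
          wsum[k] += w;
        }
      }
    }
  }
  return List::create(_["vol"] = vol, _["wsum"] = wsum);
}

// Normalized pixel weight of one measurement of an axial scan (for the
// redundancy invariant): w/Omega of the measurement of voxel (x,y,z) taken
// by spot si (0-based) at angle b. NA if unmeasured.
// [[Rcpp::export]]
double cpp_applied_weight(double x, double y, double z, double b, int si,
                          NumericVector spots_z, double R, double D,
                          double dgamma, double row_pitch_phys, int nrow_det,
                          int nchan, double cone_k, double zt_ref) {
  BPPar bp;
  bp.R = R; bp.D = D; bp.rpp = row_pitch_phys; bp.nrow = nrow_det;
  bp.spots = std::vector<double>(spots_z.begin(), spots_z.end());
  bp.zt_ref = zt_ref; bp.cone_k = cone_k;
  double sb = std::sin(b), cb = std::cos(b);
  double Sx = -R * sb, Sy = R * cb;
  double wx = x - Sx, wy = y - Sy;
  double g = std::atan2(-(wx * cb + wy * sb), wx * sb - wy * cb);
  double cf = g / dgamma + 0.5 * (nchan - 1);
  if (cf < 0.0 || cf > nchan - 1) return NA_REAL;
  MeasW self = measurement_weight(bp, x, y, z, b, si, true);
  if (!self.ok) return NA_REAL;
  return self.w / weight_set_total(bp, x, y, z, b, true);
}
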