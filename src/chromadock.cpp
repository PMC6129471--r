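// Core numerics for rigid-body Brownian-dynamics docking:
//  - screened-Coulomb (Debye-Hueckel) potential grids by superposition
//  - trilinear interpolation of potential and field with an analytic
//    monopole tail outside the grid
//  - the Ermak-McCammon propagator with excluded-volume rejection
//  - the capacity-limited, energy-ranked, RMSD-deduplicated encounter
//    archive (recorder)
//  - closed-form rigid-pose RMSD (no re-superposition; both poses are
//    expressed in the fixed nucleosome frame)
//
// Pose convention matches the R side: world = R(q) * y + t, where y are
// body-frame coordinates centered at the solute's geometric center and t
// is the world position of that center. Quaternions are (w, x, y, z).
//
// All energies are in kT, lengths in Angstrom, forces in kT/A.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- helpers

static inline void quat_to_R(const double* q, double* R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_mul(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline void quat_normalize(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n;
}

struct GridView {
  const double* v;
  double ox, oy, oz, sp;
  int nx, ny, nz;
};

static GridView as_grid(const List& g, bool with_values = true) {
  GridView gv;
  NumericVector origin = g["origin"];
  IntegerVector dims = g["dims"];
  if (with_values) {
    NumericVector vals = g["values"];
    gv.v = REAL(vals);
  } else {
    gv.v = NULL;
  }
  gv.ox = origin[0]; gv.oy = origin[1]; gv.oz = origin[2];
  gv.sp = as<double>(g["spacing"]);
  gv.nx = dims[0]; gv.ny = dims[1]; gv.nz = dims[2];
  return gv;
}

// trilinear interpolation of value and gradient; returns false outside grid
static inline bool grid_sample(const GridView& g, double x, double y, double z,
                               double& phi, double* grad) {
  double u = (x - g.ox) / g.sp, v = (y - g.oy) / g.sp, w = (z - g.oz) / g.sp;
  int i = (int)std::floor(u), j = (int)std::floor(v), k = (int)std::floor(w);
  if (i < 0 || j < 0 || k < 0 || i > g.nx - 2 || j > g.ny - 2 || k > g.nz - 2)
    return false;
  double fx = u - i, fy = v - j, fz = w - k;
  const double* p = g.v;
  long nx = g.nx, nxy = (long)g.nx * g.ny;
  long base = i + nx * j + nxy * k;
  double c000 = p[base],            c100 = p[base + 1];
  double c010 = p[base + nx],       c110 = p[base + nx + 1];
  double c001 = p[base + nxy],      c101 = p[base + nxy + 1];
  double c011 = p[base + nx + nxy], c111 = p[base + nx + nxy + 1];
  double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  phi = c0 + fz * (c1 - c0);
  // analytic gradient of the trilinear interpolant
  double dx00 = c100 - c000, dx10 = c110 - c010, dx01 = c101 - c001, dx11 = c111 - c011;
  double dx0 = dx00 + fy * (dx10 - dx00), dx1 = dx01 + fy * (dx11 - dx01);
  grad[0] = (dx0 + fz * (dx1 - dx0)) / g.sp;
  double dy0 = (c10 - c00), dy1 = (c11 - c01);
  grad[1] = (dy0 + fz * (dy1 - dy0)) / g.sp;
  grad[2] = (c1 - c0) / g.sp;
  return true;
}

// screened monopole tail of a source solute: phi = pref * Q * exp(-kappa r)/r;
// beyond ~14 Debye lengths the screened interaction is far below 1e-4 kT
// and is treated as zero
static inline void tail_sample(double dx, double dy, double dz, double tailQ,
                               double kappa, double pref,
                               double& phi, double* grad) {
  double r2 = dx * dx + dy * dy + dz * dz;
  double r = std::sqrt(r2);
  if (r < 1e-6 || kappa * r > 14.0) {
    phi = 0; grad[0] = grad[1] = grad[2] = 0; return;
  }
  double e = pref * tailQ * std::exp(-kappa * r) / r;
  phi = e;
  double dphi_dr = -e * (kappa + 1.0 / r);
  grad[0] = dphi_dr * dx / r; grad[1] = dphi_dr * dy / r; grad[2] = dphi_dr * dz / r;
}

// ------------------------------------------------------------ DH grid

// [[Rcpp::export]]
List dh_grid_cpp(NumericMatrix pos, NumericVector q, NumericVector radii,
                 NumericVector origin, double spacing, IntegerVector dims,
                 double kappa, double pref, double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ncell = (long)nx * ny * nz;
  NumericVector values((R_xlen_t)ncell);
  double* v = REAL(values);
  int n_clamped = 0;
  double cut2 = (cutoff > 0 && R_finite(cutoff)) ? cutoff * cutoff : R_PosInf;
  for (int a = 0; a < pos.nrow(); ++a) {
    double qa = q[a];
    if (qa == 0) continue;
    double ax = pos(a, 0), ay = pos(a, 1), az = pos(a, 2), ra = radii[a];
    double denom = 1.0 + kappa * ra;
    double clampr = (ra > 0) ? ra : 0.5 * spacing;
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      double dz = origin[2] + k * spacing - az, dz2 = dz * dz;
      for (int j = 0; j < ny; ++j) {
        double dy = origin[1] + j * spacing - ay, dyz2 = dy * dy + dz2;
        for (int i = 0; i < nx; ++i, ++idx) {
          double dx = origin[0] + i * spacing - ax;
          double r2 = dx * dx + dyz2;
          if (r2 > cut2) continue;
          double r = std::sqrt(r2);
          if (r < clampr) { r = clampr; ++n_clamped; }
          v[idx] += pref * qa * std::exp(-kappa * (r - ra)) / (denom * r);
        }
      }
    }
  }
  return List::create(_["values"] = values, _["n_clamped"] = n_clamped);
}

// ------------------------------------------- energy / force of a site set

// Sites are world-frame positions of point charges evaluated in a fixed
// grid; out-of-grid sites use the analytic monopole tail of the grid's
// source solute. Torque is taken about `center`.
// [[Rcpp::export]]
List grid_field_cpp(List grid, NumericMatrix sites, NumericVector q,
                    NumericVector tail_center, double tail_Q,
                    double kappa, double pref, NumericVector center) {
  GridView g = as_grid(grid);
  double E = 0, F[3] = {0, 0, 0}, T[3] = {0, 0, 0};
  double phi, grad[3];
  for (int s = 0; s < sites.nrow(); ++s) {
    double x = sites(s, 0), y = sites(s, 1), z = sites(s, 2);
    if (!grid_sample(g, x, y, z, phi, grad)) {
      tail_sample(x - tail_center[0], y - tail_center[1], z - tail_center[2],
                  tail_Q, kappa, pref, phi, grad);
    }
    double qs = q[s];
    E += qs * phi;
    double fx = -qs * grad[0], fy = -qs * grad[1], fz = -qs * grad[2];
    F[0] += fx; F[1] += fy; F[2] += fz;
    double rx = x - center[0], ry = y - center[1], rz = z - center[2];
    T[0] += ry * fz - rz * fy;
    T[1] += rz * fx - rx * fz;
    T[2] += rx * fy - ry * fx;
  }
  return List::create(_["energy"] = E,
                      _["force"] = NumericVector::create(F[0], F[1], F[2]),
                      _["torque"] = NumericVector::create(T[0], T[1], T[2]));
}

// ------------------------------------------------------------- recorder

struct Recorder {
  int capacity, n;
  double dedup, cell;
  double seen;
  double M[9], ybar[3], trM;
  int Natoms;
  std::vector<double> q, t, R, w, e; // per record: 4, 3, 9, 3, 1
  std::vector<double> cnt;
  std::vector<int> traj, step;
  int worst;
  std::unordered_map<long long, std::vector<int> > hash;

  long long key_of(const double* tt) const {
    long long ix = (long long)std::floor(tt[0] / cell) + 1000000;
    long long iy = (long long)std::floor(tt[1] / cell) + 1000000;
    long long iz = (long long)std::floor(tt[2] / cell) + 1000000;
    return (ix * 2097152LL + iy) * 2097152LL + iz;
  }
  void hash_add(int idx) { hash[key_of(&t[3 * idx])].push_back(idx); }
  void hash_remove(int idx) {
    std::vector<int>& v = hash[key_of(&t[3 * idx])];
    for (size_t i = 0; i < v.size(); ++i)
      if (v[i] == idx) { v.erase(v.begin() + i); return; }
  }

  double rmsd2(const double* R1, const double* w1, const double* t1, int j) const {
    const double* R2 = &R[9 * j];
    const double* w2 = &w[3 * j];
    const double* t2 = &t[3 * j];
    // tr(R1 M R2^T) = sum_ij (R1 M)_ij R2_ij
    double A[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        A[3 * r + c] = R1[3 * r + 0] * M[0 + c] + R1[3 * r + 1] * M[3 + c] +
                       R1[3 * r + 2] * M[6 + c];
    double tr = 0;
    for (int i = 0; i < 9; ++i) tr += A[i] * R2[i];
    double d0 = t1[0] - t2[0], d1 = t1[1] - t2[1], d2 = t1[2] - t2[2];
    double cross = d0 * (w1[0] - w2[0]) + d1 * (w1[1] - w2[1]) + d2 * (w1[2] - w2[2]);
    double val = 2.0 * (trM - tr) / Natoms + 2.0 * cross + d0 * d0 + d1 * d1 + d2 * d2;
    return val > 0 ? val : 0;
  }

  void recompute_worst() {
    worst = -1;
    for (int i = 0; i < n; ++i)
      if (worst < 0 || e[i] > e[worst]) worst = i;
  }

  void set_record(int idx, const double* qq, const double* tt, const double* RR,
                  const double* ww, double ee, double cc, int tj, int st) {
    for (int k = 0; k < 4; ++k) q[4 * idx + k] = qq[k];
    for (int k = 0; k < 3; ++k) t[3 * idx + k] = tt[k];
    for (int k = 0; k < 9; ++k) R[9 * idx + k] = RR[k];
    for (int k = 0; k < 3; ++k) w[3 * idx + k] = ww[k];
    e[idx] = ee; cnt[idx] = cc; traj[idx] = tj; step[idx] = st;
  }

  // apply one encounter event under the recording / substitution /
  // counting rules; returns an action code (0 drop, 1 new, 2 substitute,
  // 3 count-increment)
  int update(const double* qq, const double* tt, double ee, int tj, int st) {
    seen += 1;
    double R1[9], w1[3];
    quat_to_R(qq, R1);
    for (int k = 0; k < 3; ++k)
      w1[k] = R1[3 * k] * ybar[0] + R1[3 * k + 1] * ybar[1] + R1[3 * k + 2] * ybar[2];
    // neighbors within dedup RMSD (spatial hash query)
    int closest = -1, closest_lower = -1;
    double best = R_PosInf, best_lower = R_PosInf;
    long long ix = (long long)std::floor(tt[0] / cell) + 1000000;
    long long iy = (long long)std::floor(tt[1] / cell) + 1000000;
    long long iz = (long long)std::floor(tt[2] / cell) + 1000000;
    double dd = dedup * dedup;
    for (long long a = ix - 1; a <= ix + 1; ++a)
      for (long long b = iy - 1; b <= iy + 1; ++b)
        for (long long c = iz - 1; c <= iz + 1; ++c) {
          std::unordered_map<long long, std::vector<int> >::iterator it =
            hash.find((a * 2097152LL + b) * 2097152LL + c);
          if (it == hash.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            int j = v[m];
            double r2 = rmsd2(R1, w1, tt, j);
            if (r2 <= dd) {
              if (r2 < best || (r2 == best && j < closest)) { best = r2; closest = j; }
              if (e[j] < ee &&
                  (r2 < best_lower || (r2 == best_lower && j < closest_lower))) {
                best_lower = r2; closest_lower = j;
              }
            }
          }
        }
    if (closest < 0) {
      // no recorded complex within the dedup RMSD: a new record if its
      // energy is within the `capacity` most favorable
      if (n < capacity) {
        set_record(n, qq, tt, R1, w1, ee, 1, tj, st);
        hash_add(n);
        if (worst < 0 || ee > e[worst]) worst = n;
        ++n;
        return 1;
      } else if (ee < e[worst]) {
        hash_remove(worst);
        set_record(worst, qq, tt, R1, w1, ee, 1, tj, st);
        hash_add(worst);
        recompute_worst();
        return 1;
      }
      return 0;
    }
    if (closest_lower >= 0) {
      // a recorded complex nearby already has lower energy: add to its count
      cnt[closest_lower] += 1;
      return 3;
    }
    // candidate has lower energy than every neighbor: substitute the closest
    bool was_worst = (closest == worst);
    hash_remove(closest);
    set_record(closest, qq, tt, R1, w1, ee, cnt[closest] + 1, tj, st);
    hash_add(closest);
    if (was_worst) recompute_worst();
    return 2;
  }
};

static Recorder recorder_from_state(const List& state, const List& rparams) {
  Recorder rec;
  rec.capacity = as<int>(rparams["capacity"]);
  rec.dedup = as<double>(rparams["dedup_rmsd"]);
  NumericMatrix M = rparams["M"];
  NumericVector ybar = rparams["ybar"];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) rec.M[3 * r + c] = M(r, c);
  rec.trM = rec.M[0] + rec.M[4] + rec.M[8];
  rec.ybar[0] = ybar[0]; rec.ybar[1] = ybar[1]; rec.ybar[2] = ybar[2];
  rec.Natoms = as<int>(rparams["n_atoms"]);
  double yn = std::sqrt(rec.ybar[0] * rec.ybar[0] + rec.ybar[1] * rec.ybar[1] +
                        rec.ybar[2] * rec.ybar[2]);
  rec.cell = rec.dedup + 2.0 * yn + 1e-9; // |t1-t2| <= dedup + 2|ybar| when RMSD <= dedup
  rec.q.assign(4 * rec.capacity, 0.0); rec.t.assign(3 * rec.capacity, 0.0);
  rec.R.assign(9 * rec.capacity, 0.0); rec.w.assign(3 * rec.capacity, 0.0);
  rec.e.assign(rec.capacity, 0.0); rec.cnt.assign(rec.capacity, 0.0);
  rec.traj.assign(rec.capacity, 0); rec.step.assign(rec.capacity, 0);
  rec.n = as<int>(state["n"]);
  rec.seen = as<double>(state["seen"]);
  if (rec.n > 0) {
    NumericMatrix Q = state["Q"], T = state["T"];
    NumericVector E = state["E"], CNT = state["count"];
    IntegerVector TJ = state["traj"], ST = state["step"];
    for (int i = 0; i < rec.n; ++i) {
      double qq[4] = {Q(i, 0), Q(i, 1), Q(i, 2), Q(i, 3)};
      double tt[3] = {T(i, 0), T(i, 1), T(i, 2)};
      double RR[9], ww[3];
      quat_to_R(qq, RR);
      for (int k = 0; k < 3; ++k)
        ww[k] = RR[3 * k] * rec.ybar[0] + RR[3 * k + 1] * rec.ybar[1] +
                RR[3 * k + 2] * rec.ybar[2];
      rec.set_record(i, qq, tt, RR, ww, E[i], CNT[i], TJ[i], ST[i]);
      rec.hash_add(i);
    }
  }
  rec.recompute_worst();
  return rec;
}

static List recorder_to_state(const Recorder& rec) {
  NumericMatrix Q(rec.n, 4), T(rec.n, 3);
  NumericVector E(rec.n), CNT(rec.n);
  IntegerVector TJ(rec.n), ST(rec.n);
  for (int i = 0; i < rec.n; ++i) {
    for (int k = 0; k < 4; ++k) Q(i, k) = rec.q[4 * i + k];
    for (int k = 0; k < 3; ++k) T(i, k) = rec.t[3 * i + k];
    E[i] = rec.e[i]; CNT[i] = rec.cnt[i]; TJ[i] = rec.traj[i]; ST[i] = rec.step[i];
  }
  return List::create(_["n"] = rec.n, _["Q"] = Q, _["T"] = T, _["E"] = E,
                      _["count"] = CNT, _["traj"] = TJ, _["step"] = ST,
                      _["seen"] = rec.seen);
}

// single-event update (functional interface used by update_recorded_set)
// [[Rcpp::export]]
List recorder_update_cpp(List state, NumericVector q, NumericVector t,
                         double energy, int traj, int step, List rparams) {
  Recorder rec = recorder_from_state(state, rparams);
  double qq[4] = {q[0], q[1], q[2], q[3]};
  double tt[3] = {t[0], t[1], t[2]};
  int action = rec.update(qq, tt, energy, traj, step);
  List out = recorder_to_state(rec);
  out["action"] = action;
  return out;
}

// ----------------------------------------------------- BD trajectory

static inline bool overlap_check(const GridView& ex, const int* occ,
                                 const NumericMatrix& body, const double* R,
                                 const double* t) {
  for (int a = 0; a < body.nrow(); ++a) {
    double bx = body(a, 0), by = body(a, 1), bz = body(a, 2);
    double x = R[0] * bx + R[1] * by + R[2] * bz + t[0];
    double y = R[3] * bx + R[4] * by + R[5] * bz + t[1];
    double z = R[6] * bx + R[7] * by + R[8] * bz + t[2];
    int i = (int)std::floor((x - ex.ox) / ex.sp + 0.5);
    int j = (int)std::floor((y - ex.oy) / ex.sp + 0.5);
    int k = (int)std::floor((z - ex.oz) / ex.sp + 0.5);
    if (i < 0 || j < 0 || k < 0 || i >= ex.nx || j >= ex.ny || k >= ex.nz) continue;
    if (occ[i + (long)ex.nx * j + (long)ex.nx * ex.ny * k]) return true;
  }
  return false;
}

// energy, force and torque on the mobile LH at pose (R, t)
static void lh_field(const double* R, const double* t,
                     const GridView& gnuc, const NumericMatrix& lh_sites,
                     const NumericVector& lh_q,
                     const double* nuc_center, double nuc_Q,
                     bool symmetrized, const GridView* glh,
                     const NumericMatrix& nuc_sites, const NumericVector& nuc_q,
                     double lh_Q, double kappa, double pref,
                     double& E, double* F, double* T) {
  E = 0; F[0] = F[1] = F[2] = 0; T[0] = T[1] = T[2] = 0;
  double phi, grad[3];
  // A<-B: LH effective charges in the nucleosome grid
  for (int s = 0; s < lh_sites.nrow(); ++s) {
    double bx = lh_sites(s, 0), by = lh_sites(s, 1), bz = lh_sites(s, 2);
    double rx = R[0] * bx + R[1] * by + R[2] * bz;
    double ry = R[3] * bx + R[4] * by + R[5] * bz;
    double rz = R[6] * bx + R[7] * by + R[8] * bz;
    double x = rx + t[0], y = ry + t[1], z = rz + t[2];
    if (!grid_sample(gnuc, x, y, z, phi, grad))
      tail_sample(x - nuc_center[0], y - nuc_center[1], z - nuc_center[2],
                  nuc_Q, kappa, pref, phi, grad);
    double qs = lh_q[s];
    E += qs * phi;
    double fx = -qs * grad[0], fy = -qs * grad[1], fz = -qs * grad[2];
    F[0] += fx; F[1] += fy; F[2] += fz;
    T[0] += ry * fz - rz * fy; T[1] += rz * fx - rx * fz; T[2] += rx * fy - ry * fx;
  }
  if (!symmetrized) return;
  // B<-A: nucleosome charges in the (co-moving) LH grid; average the two
  double E2 = 0, F2[3] = {0, 0, 0}, T2[3] = {0, 0, 0};
  for (int s = 0; s < nuc_sites.nrow(); ++s) {
    double dx = nuc_sites(s, 0) - t[0], dy = nuc_sites(s, 1) - t[1],
           dz = nuc_sites(s, 2) - t[2];
    // body-frame position of the nucleosome charge: u = R^T d
    double ux = R[0] * dx + R[3] * dy + R[6] * dz;
    double uy = R[1] * dx + R[4] * dy + R[7] * dz;
    double uz = R[2] * dx + R[5] * dy + R[8] * dz;
    double qs = nuc_q[s];
    if (glh && grid_sample(*glh, ux, uy, uz, phi, grad)) {
      E2 += qs * phi;
      // force on the LH from this term: + q R grad_u phi
      double gx = R[0] * grad[0] + R[1] * grad[1] + R[2] * grad[2];
      double gy = R[3] * grad[0] + R[4] * grad[1] + R[5] * grad[2];
      double gz = R[6] * grad[0] + R[7] * grad[1] + R[8] * grad[2];
      double fx = qs * gx, fy = qs * gy, fz = qs * gz;
      F2[0] += fx; F2[1] += fy; F2[2] += fz;
      T2[0] += dy * fz - dz * fy; T2[1] += dz * fx - dx * fz; T2[2] += dx * fy - dy * fx;
    } else {
      // monopole tail of the LH, centered at t: central force, no torque
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) continue;
      double ephi = pref * lh_Q * std::exp(-kappa * r) / r;
      E2 += qs * ephi;
      double dphi_dr = -ephi * (kappa + 1.0 / r);
      double fmag = qs * dphi_dr; // F_LH = q phi'(r) rhat, rhat = d/r
      F2[0] += fmag * dx / r; F2[1] += fmag * dy / r; F2[2] += fmag * dz / r;
    }
  }
  E = 0.5 * (E + E2);
  F[0] = 0.5 * (F[0] + F2[0]); F[1] = 0.5 * (F[1] + F2[1]); F[2] = 0.5 * (F[2] + F2[2]);
  T[0] = 0.5 * (T[0] + T2[0]); T[1] = 0.5 * (T[1] + T2[1]); T[2] = 0.5 * (T[2] + T2[2]);
}

// One full BD trajectory: start on the sphere, propagate, record
// encounters into the archive, terminate at the stop sphere. Uses the R
// random-number stream (seed from R with set.seed before the call).
// [[Rcpp::export]]
List bd_traj_cpp(List state, List params) {
  // unpack
  List gnuc_l = params["nuc_grid"];
  GridView gnuc = as_grid(gnuc_l);
  NumericMatrix lh_sites = params["lh_sites"]; // body frame
  NumericVector lh_q = params["lh_site_q"];
  NumericMatrix lh_body = params["lh_atoms"];  // body frame, for exclusion
  List ex_l = params["exclusion"];
  GridView ex = as_grid(ex_l, false);
  IntegerVector occ_v = ex_l["occupancy"];
  const int* occ = INTEGER(occ_v);
  NumericVector nc = params["nuc_center"];
  NumericVector dp = params["dyad_point"];
  double nuc_Q = as<double>(params["nuc_Q"]);
  double lh_Q = as<double>(params["lh_Q"]);
  double kappa = as<double>(params["kappa"]);
  double pref = as<double>(params["pref"]);
  bool symmetrized = as<bool>(params["symmetrized"]);
  GridView glh; const GridView* glh_p = NULL;
  NumericMatrix nuc_sites(0, 3); NumericVector nuc_q(0);
  if (symmetrized) {
    List glh_l = params["lh_grid"];
    glh = as_grid(glh_l); glh_p = &glh;
    nuc_sites = as<NumericMatrix>(params["nuc_sites"]);
    nuc_q = as<NumericVector>(params["nuc_site_q"]);
  }
  double dt = as<double>(params["timestep"]);
  double Dt = as<double>(params["D_trans"]);
  double Dr = as<double>(params["D_rot"]);
  double start_r = as<double>(params["start_radius"]);
  double stop_r = as<double>(params["stop_radius"]);
  double c2c_max = as<double>(params["encounter_c2c_max"]);
  double dyad_max = as<double>(params["encounter_dyad_max"]);
  double max_steps = as<double>(params["max_steps"]);
  double max_disp = as<double>(params["max_step_displacement"]);
  int traj_id = as<int>(params["traj_id"]);
  bool collect = as<bool>(params["collect_events"]);
  List rparams = params["recorder"];

  Recorder rec = recorder_from_state(state, rparams);

  double sig_t = std::sqrt(2.0 * Dt * dt);
  double sig_r = std::sqrt(2.0 * Dr * dt);

  // start: uniform point on the start sphere, uniform orientation
  double t[3];
  {
    double n0 = norm_rand(), n1 = norm_rand(), n2 = norm_rand();
    double nn = std::sqrt(n0 * n0 + n1 * n1 + n2 * n2);
    while (nn < 1e-12) {
      n0 = norm_rand(); n1 = norm_rand(); n2 = norm_rand();
      nn = std::sqrt(n0 * n0 + n1 * n1 + n2 * n2);
    }
    t[0] = nc[0] + start_r * n0 / nn;
    t[1] = nc[1] + start_r * n1 / nn;
    t[2] = nc[2] + start_r * n2 / nn;
  }
  double q[4];
  {
    double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
    double s1 = std::sqrt(1 - u1), s2 = std::sqrt(u1);
    q[0] = s1 * std::sin(2 * M_PI * u2); q[1] = s1 * std::cos(2 * M_PI * u2);
    q[2] = s2 * std::sin(2 * M_PI * u3); q[3] = s2 * std::cos(2 * M_PI * u3);
  }
  double R[9];
  quat_to_R(q, R);

  std::vector<double> ev;
  double steps = 0, rejections = 0, events = 0;
  std::string exit_reason = "max_steps";
  double E = 0, F[3], T[3];
  bool have_field = false;

  while (steps < max_steps) {
    // field at the current pose: drives this step's move, and is the
    // energy recorded if the current pose is an encounter complex
    if (!have_field) {
      lh_field(R, t, gnuc, lh_sites, lh_q, &nc[0], nuc_Q, symmetrized, glh_p,
               nuc_sites, nuc_q, lh_Q, kappa, pref, E, F, T);
      have_field = true;
    }
    // a rejected move leaves the pose in place for one time step, so the
    // same pose can be recorded (counted) more than once
    {
      double dcx = t[0] - nc[0], dcy = t[1] - nc[1], dcz = t[2] - nc[2];
      double c2c2 = dcx * dcx + dcy * dcy + dcz * dcz;
      if (c2c2 < c2c_max * c2c_max) {
        double ddx = t[0] - dp[0], ddy = t[1] - dp[1], ddz = t[2] - dp[2];
        if (ddx * ddx + ddy * ddy + ddz * ddz < dyad_max * dyad_max) {
          rec.update(q, t, E, traj_id, (int)steps);
          events += 1;
          if (collect) {
            for (int k = 0; k < 4; ++k) ev.push_back(q[k]);
            for (int k = 0; k < 3; ++k) ev.push_back(t[k]);
            ev.push_back(E);
            ev.push_back(steps);
          }
        }
      }
    }
    // trial move (Ermak-McCammon)
    double dxv[3], dphi[3];
    for (int k = 0; k < 3; ++k) {
      dxv[k] = Dt * F[k] * dt + sig_t * norm_rand();
      dphi[k] = Dr * T[k] * dt + sig_r * norm_rand();
    }
    double disp = std::sqrt(dxv[0] * dxv[0] + dxv[1] * dxv[1] + dxv[2] * dxv[2]);
    if (disp > max_disp) {
      exit_reason = "step_too_large";
      break;
    }
    double t_new[3] = {t[0] + dxv[0], t[1] + dxv[1], t[2] + dxv[2]};
    double ang = std::sqrt(dphi[0] * dphi[0] + dphi[1] * dphi[1] + dphi[2] * dphi[2]);
    double q_new[4];
    if (ang > 1e-14) {
      double half = 0.5 * ang, s = std::sin(half) / ang;
      double dq[4] = {std::cos(half), s * dphi[0], s * dphi[1], s * dphi[2]};
      quat_mul(dq, q, q_new);
      quat_normalize(q_new);
    } else {
      for (int k = 0; k < 4; ++k) q_new[k] = q[k];
    }
    double R_new[9];
    quat_to_R(q_new, R_new);
    steps += 1;
    // excluded volume: reject-and-redraw (position unchanged, new noise)
    if (overlap_check(ex, occ, lh_body, R_new, t_new)) {
      rejections += 1;
      continue;
    }
    for (int k = 0; k < 3; ++k) t[k] = t_new[k];
    for (int k = 0; k < 4; ++k) q[k] = q_new[k];
    for (int k = 0; k < 9; ++k) R[k] = R_new[k];
    have_field = false;
    double dcx = t[0] - nc[0], dcy = t[1] - nc[1], dcz = t[2] - nc[2];
    if (dcx * dcx + dcy * dcy + dcz * dcz >= stop_r * stop_r) {
      exit_reason = "stopped";
      break;
    }
  }

  List out = recorder_to_state(rec);
  out["exit_reason"] = exit_reason;
  out["steps"] = steps;
  out["rejections"] = rejections;
  out["events"] = events;
  if (collect) {
    int nev = (int)(ev.size() / 9);
    NumericMatrix em(nev, 9);
    for (int i = 0; i < nev; ++i)
      for (int k = 0; k < 9; ++k) em(i, k) = ev[9 * i + k];
    out["event_log"] = em;
  }
  return out;
}

// ------------------------------------------------- propagator physics

// Free / harmonically-restrained diffusion with the same update rule as
// the docking propagator; returns final positions of all replicas.
// Used to check the Einstein relation and Boltzmann sampling.
// [[Rcpp::export]]
NumericMatrix bd_diffusion_cpp(int n_replicas, int n_steps, double dt,
                               double D_trans, double k_harm) {
  NumericMatrix out(n_replicas, 3);
  double sig = std::sqrt(2.0 * D_trans * dt);
  for (int r = 0; r < n_replicas; ++r) {
    double x[3] = {0, 0, 0};
    for (int s = 0; s < n_steps; ++s)
      for (int k = 0; k < 3; ++k)
        x[k] += D_trans * (-k_harm * x[k]) * dt + sig * norm_rand();
    out(r, 0) = x[0]; out(r, 1) = x[1]; out(r, 2) = x[2];
  }
  return out;
}

// ------------------------------------------------- pose RMSD matrix

// closed-form rigid-pose RMSD for all pose pairs (fixed-frame, no
// re-superposition): RMSD^2 = 2(trM - tr(R1 M R2^T))/N
//                            + 2 d.(R1 ybar - R2 ybar) + |d|^2
// [[Rcpp::export]]
NumericMatrix pose_rmsd_mat_cpp(NumericMatrix Q, NumericMatrix T,
                                NumericMatrix M, NumericVector ybar, int n_atoms) {
  int n = Q.nrow();
  std::vector<double> R(9 * n), w(3 * n);
  double Mm[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) Mm[3 * r + c] = M(r, c);
  double trM = Mm[0] + Mm[4] + Mm[8];
  for (int i = 0; i < n; ++i) {
    double qq[4] = {Q(i, 0), Q(i, 1), Q(i, 2), Q(i, 3)};
    quat_to_R(qq, &R[9 * i]);
    for (int k = 0; k < 3; ++k)
      w[3 * i + k] = R[9 * i + 3 * k] * ybar[0] + R[9 * i + 3 * k + 1] * ybar[1] +
                     R[9 * i + 3 * k + 2] * ybar[2];
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    double A[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        A[3 * r + c] = R[9 * i + 3 * r] * Mm[c] + R[9 * i + 3 * r + 1] * Mm[3 + c] +
                       R[9 * i + 3 * r + 2] * Mm[6 + c];
    for (int j = i + 1; j < n; ++j) {
      double tr = 0;
      for (int k = 0; k < 9; ++k) tr += A[k] * R[9 * j + k];
      double d0 = T(i, 0) - T(j, 0), d1 = T(i, 1) - T(j, 1), d2 = T(i, 2) - T(j, 2);
      double cross = d0 * (w[3 * i] - w[3 * j]) + d1 * (w[3 * i + 1] - w[3 * j + 1]) +
                     d2 * (w[3 * i + 2] - w[3 * j + 2]);
      double v = 2.0 * (trM - tr) / n_atoms + 2.0 * cross + d0 * d0 + d1 * d1 + d2 * d2;
      double rm = v > 0 ? std::sqrt(v) : 0.0;
      out(i, j) = rm; out(j, i) = rm;
    }
  }
  return out;
}
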