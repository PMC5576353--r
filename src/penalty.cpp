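#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinates are passed column-major: par = c(x_1..x_L, y_1..y_L, z_1..z_L).
// Virtual C-beta for a CA-only trace: for interior residue i,
//   u = normalize( normalize(a[i-1]-a[i]) + normalize(a[i+1]-a[i]) )
//   cb[i] = a[i] - 1.53 * u
// terminals borrow the frame of their nearest interior neighbour; glycine
// uses cb = ca.  The same construction (and its exact gradient) is used by
// both the energy reporter and the minimizer, so restraints on C-beta atoms
// are self-consistent across the package.

static const double CB_DIST = 1.53;

struct Frame {
  double u[3], u1[3], u2[3];
  double l1, l2, ns;
  bool ok;
};

static inline double norm3(const double* v) {
  return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
}

// frame of interior residue i (0-based), from CA coords
static Frame make_frame(const double* x, const double* y, const double* z,
                        int i) {
  Frame f;
  double v1[3] = {x[i - 1] - x[i], y[i - 1] - y[i], z[i - 1] - z[i]};
  double v2[3] = {x[i + 1] - x[i], y[i + 1] - y[i], z[i + 1] - z[i]};
  f.l1 = norm3(v1);
  f.l2 = norm3(v2);
  f.ok = (f.l1 > 1e-9 && f.l2 > 1e-9);
  if (!f.ok) { f.ns = 1.0; for (int k = 0; k < 3; ++k) { f.u[k] = f.u1[k] = f.u2[k] = 0.0; } f.u[0] = 1.0; return f; }
  double s[3];
  for (int k = 0; k < 3; ++k) {
    f.u1[k] = v1[k] / f.l1;
    f.u2[k] = v2[k] / f.l2;
    s[k] = f.u1[k] + f.u2[k];
  }
  f.ns = norm3(s);
  if (f.ns < 1e-8) {
    // nearly collinear neighbours: fall back to a deterministic
    // perpendicular of u1 (gradient treated as zero here)
    double p[3] = {-f.u1[1], f.u1[0], 0.0};
    double np = norm3(p);
    if (np < 1e-8) { p[0] = 0.0; p[1] = -f.u1[2]; p[2] = f.u1[1]; np = norm3(p); }
    for (int k = 0; k < 3; ++k) f.u[k] = p[k] / np;
    f.ns = -1.0; // marks degenerate frame: no gradient through u
  } else {
    for (int k = 0; k < 3; ++k) f.u[k] = s[k] / f.ns;
  }
  return f;
}

// apply (I - u u^T) g / scale
static inline void proj_perp(const double* u, const double* g, double scale,
                             double* out) {
  double du = u[0] * g[0] + u[1] * g[1] + u[2] * g[2];
  for (int k = 0; k < 3; ++k) out[k] = (g[k] - du * u[k]) / scale;
}

// [[Rcpp::export]]
NumericMatrix cpp_virtual_cbeta(NumericMatrix ca, LogicalVector is_gly) {
  int L = ca.nrow();
  NumericMatrix cb(L, 3);
  if (L < 3) {
    for (int i = 0; i < L; ++i)
      for (int k = 0; k < 3; ++k) cb(i, k) = ca(i, k);
    return cb;
  }
  std::vector<double> x(L), y(L), z(L);
  for (int i = 0; i < L; ++i) { x[i] = ca(i, 0); y[i] = ca(i, 1); z[i] = ca(i, 2); }
  std::vector<Frame> fr(L);
  for (int i = 1; i < L - 1; ++i) fr[i] = make_frame(&x[0], &y[0], &z[0], i);
  for (int i = 0; i < L; ++i) {
    int f = (i == 0) ? 1 : (i == L - 1 ? L - 2 : i);
    if (is_gly[i]) {
      cb(i, 0) = x[i]; cb(i, 1) = y[i]; cb(i, 2) = z[i];
    } else {
      cb(i, 0) = x[i] - CB_DIST * fr[f].u[0];
      cb(i, 1) = y[i] - CB_DIST * fr[f].u[1];
      cb(i, 2) = z[i] - CB_DIST * fr[f].u[2];
    }
  }
  return cb;
}

// flat-bottom quadratic penalty and analytic gradient.
// distance restraints: index vectors (0-based), atom codes 0 = CA, 1 = CB;
// dihedral restraints: q_i = first residue of a consecutive CA quadruple,
// target / tol in radians, penalised quadratically beyond tol, scaled by
// dih_scale (an angle-to-arc-length factor so angular and distance terms
// are commensurate).
// [[Rcpp::export]]
List cpp_penalty(NumericVector par, LogicalVector is_gly,
                 IntegerVector d_i, IntegerVector d_j,
                 IntegerVector d_ai, IntegerVector d_aj,
                 NumericVector d_lo, NumericVector d_hi, NumericVector d_w,
                 IntegerVector q_i, NumericVector q_target,
                 NumericVector q_tol, NumericVector q_w,
                 double dih_scale, double huber = 1e9) {
  int L = par.size() / 3;
  const double* x = &par[0];
  const double* y = &par[L];
  const double* z = &par[2 * L];
  NumericVector grad(3 * L);
  double* gx = &grad[0];
  double* gy = &grad[L];
  double* gz = &grad[2 * L];

  // --- virtual C-beta and frames ---
  std::vector<double> cbx(L), cby(L), cbz(L);
  std::vector<Frame> fr(L);
  bool have_cb = (L >= 3);
  if (have_cb) {
    for (int i = 1; i < L - 1; ++i) fr[i] = make_frame(x, y, z, i);
    for (int i = 0; i < L; ++i) {
      int f = (i == 0) ? 1 : (i == L - 1 ? L - 2 : i);
      if (is_gly[i]) { cbx[i] = x[i]; cby[i] = y[i]; cbz[i] = z[i]; }
      else {
        cbx[i] = x[i] - CB_DIST * fr[f].u[0];
        cby[i] = y[i] - CB_DIST * fr[f].u[1];
        cbz[i] = z[i] - CB_DIST * fr[f].u[2];
      }
    }
  } else {
    for (int i = 0; i < L; ++i) { cbx[i] = x[i]; cby[i] = y[i]; cbz[i] = z[i]; }
  }
  std::vector<double> gcbx(L, 0.0), gcby(L, 0.0), gcbz(L, 0.0);

  double energy = 0.0;

  // --- distance terms ---
  int nd = d_i.size();
  for (int r = 0; r < nd; ++r) {
    int i = d_i[r], j = d_j[r];
    bool bi = d_ai[r] == 1, bj = d_aj[r] == 1;
    double px = bi ? cbx[i] : x[i], py = bi ? cby[i] : y[i], pz = bi ? cbz[i] : z[i];
    double qx = bj ? cbx[j] : x[j], qy = bj ? cby[j] : y[j], qz = bj ? cbz[j] : z[j];
    double dx = px - qx, dy = py - qy, dz = pz - qz;
    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
    double g = 0.0;
    // flat-bottom quadratic, switching to a linear asymptote beyond a
    // violation of `huber` (soft-square behaviour: bounded gradients keep
    // the line search stable under grossly violated long-range restraints)
    if (dist < d_lo[r]) {
      double v = d_lo[r] - dist;
      if (v <= huber) {
        energy += d_w[r] * v * v;
        g = -2.0 * d_w[r] * v;
      } else {
        energy += d_w[r] * (2.0 * huber * v - huber * huber);
        g = -2.0 * d_w[r] * huber;
      }
    } else if (dist > d_hi[r]) {
      double v = dist - d_hi[r];
      if (v <= huber) {
        energy += d_w[r] * v * v;
        g = 2.0 * d_w[r] * v;
      } else {
        energy += d_w[r] * (2.0 * huber * v - huber * huber);
        g = 2.0 * d_w[r] * huber;
      }
    }
    if (g != 0.0 && dist > 1e-9) {
      double s = g / dist;
      double vx = s * dx, vy = s * dy, vz = s * dz;
      if (bi) { gcbx[i] += vx; gcby[i] += vy; gcbz[i] += vz; }
      else    { gx[i] += vx;  gy[i] += vy;  gz[i] += vz; }
      if (bj) { gcbx[j] -= vx; gcby[j] -= vy; gcbz[j] -= vz; }
      else    { gx[j] -= vx;  gy[j] -= vy;  gz[j] -= vz; }
    }
  }

  // --- pseudo-dihedral terms ---
  int nq = q_i.size();
  for (int r = 0; r < nq; ++r) {
    int i = q_i[r];
    double p1[3] = {x[i], y[i], z[i]};
    double p2[3] = {x[i + 1], y[i + 1], z[i + 1]};
    double p3[3] = {x[i + 2], y[i + 2], z[i + 2]};
    double p4[3] = {x[i + 3], y[i + 3], z[i + 3]};
    double b1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double b2[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
    double b3[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                    b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                    b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double nb2 = norm3(b2);
    double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
    double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
    if (nb2 < 1e-9 || n1sq < 1e-12 || n2sq < 1e-12) continue;
    double n1xn2[3] = {n1[1] * n2[2] - n1[2] * n2[1],
                       n1[2] * n2[0] - n1[0] * n2[2],
                       n1[0] * n2[1] - n1[1] * n2[0]};
    double ycomp = (n1xn2[0] * b2[0] + n1xn2[1] * b2[1] +
                    n1xn2[2] * b2[2]) / nb2;
    double xcomp = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double theta = std::atan2(ycomp, xcomp);
    double delta = theta - q_target[r];
    while (delta > M_PI) delta -= 2.0 * M_PI;
    while (delta <= -M_PI) delta += 2.0 * M_PI;
    double excess = std::fabs(delta) - q_tol[r];
    if (excess <= 0.0) continue;
    double sc = dih_scale;
    energy += q_w[r] * sc * sc * excess * excess;
    double dEdtheta = 2.0 * q_w[r] * sc * sc * excess * (delta > 0 ? 1.0 : -1.0);
    // dtheta/dp for the atan2((n1 x n2) . b2hat, n1 . n2) convention
    double F1[3], F4[3];
    for (int k = 0; k < 3; ++k) {
      F1[k] = -nb2 / n1sq * n1[k];
      F4[k] = nb2 / n2sq * n2[k];
    }
    double s1 = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (nb2 * nb2);
    double s2 = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (nb2 * nb2);
    // near-collinear triples make |n|^2 -> 0 and the analytic gradient
    // singular; clamp its magnitude (exact whenever angles are sane)
    double fmax = std::max(norm3(F1), norm3(F4));
    if (fmax > 20.0) {
      double cscale = 20.0 / fmax;
      for (int k = 0; k < 3; ++k) { F1[k] *= cscale; F4[k] *= cscale; }
    }
    double F2[3], F3[3];
    for (int k = 0; k < 3; ++k) {
      F2[k] = -(1.0 + s1) * F1[k] + s2 * F4[k];
      F3[k] = s1 * F1[k] - (1.0 + s2) * F4[k];
    }
    gx[i] += dEdtheta * F1[0]; gy[i] += dEdtheta * F1[1]; gz[i] += dEdtheta * F1[2];
    gx[i + 1] += dEdtheta * F2[0]; gy[i + 1] += dEdtheta * F2[1]; gz[i + 1] += dEdtheta * F2[2];
    gx[i + 2] += dEdtheta * F3[0]; gy[i + 2] += dEdtheta * F3[1]; gz[i + 2] += dEdtheta * F3[2];
    gx[i + 3] += dEdtheta * F4[0]; gy[i + 3] += dEdtheta * F4[1]; gz[i + 3] += dEdtheta * F4[2];
  }

  // --- backprop C-beta gradients to C-alpha ---
  if (have_cb) {
    for (int i = 0; i < L; ++i) {
      double g[3] = {gcbx[i], gcby[i], gcbz[i]};
      if (g[0] == 0.0 && g[1] == 0.0 && g[2] == 0.0) continue;
      if (is_gly[i]) {
        gx[i] += g[0]; gy[i] += g[1]; gz[i] += g[2];
        continue;
      }
      // cb_i = a_i - d * u(frame f)
      gx[i] += g[0]; gy[i] += g[1]; gz[i] += g[2];
      int f = (i == 0) ? 1 : (i == L - 1 ? L - 2 : i);
      const Frame& F = fr[f];
      if (!F.ok || F.ns < 0.0) continue; // degenerate frame: no u-gradient
      // gs = -d * (I - u u^T) g / ns
      double gs[3];
      proj_perp(F.u, g, F.ns / (-CB_DIST), gs);
      // distribute through s = u1 + u2
      double t1[3], t2[3];
      proj_perp(F.u1, gs, F.l1, t1); // contribution to a_{f-1}
      proj_perp(F.u2, gs, F.l2, t2); // contribution to a_{f+1}
      gx[f - 1] += t1[0]; gy[f - 1] += t1[1]; gz[f - 1] += t1[2];
      gx[f + 1] += t2[0]; gy[f + 1] += t2[1]; gz[f + 1] += t2[2];
      gx[f] -= t1[0] + t2[0]; gy[f] -= t1[1] + t2[1]; gz[f] -= t1[2] + t2[2];
    }
  }

  return List::create(_["energy"] = energy, _["grad"] = grad);
}

// In-place triangle-inequality smoothing of an upper-bound matrix
// (all-pairs shortest path).  Returns the smoothed copy.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_upper(NumericMatrix ub) {
  int L = ub.nrow();
  NumericMatrix m(clone(ub));
  for (int k = 0; k < L; ++k) {
    for (int i = 0; i < L; ++i) {
      double mik = m(i, k);
      if (!R_finite(mik)) continue;
      for (int j = 0; j < L; ++j) {
        double v = mik + m(k, j);
        if (v < m(i, j)) m(i, j) = v;
      }
    }
  }
  return m;
}

// Raise lower bounds via the inverse triangle rule
// lb(i,j) >= lb(i,k) - ub(k,j), given a smoothed ub.  A few passes.
// [[Rcpp::export]]
NumericMatrix cpp_smooth_lower(NumericMatrix lb, NumericMatrix ub,
                               int passes = 2) {
  int L = lb.nrow();
  NumericMatrix m(clone(lb));
  for (int p = 0; p < passes; ++p) {
    for (int k = 0; k < L; ++k) {
      for (int i = 0; i < L; ++i) {
        double a = m(i, k), u = ub(i, k);
        for (int j = 0; j < L; ++j) {
          double v1 = a - ub(k, j);
          double v2 = m(k, j) - u;
          double v = v1 > v2 ? v1 : v2;
          if (v > m(i, j)) m(i, j) = v;
        }
      }
    }
  }
  return m;
}

// minimum image distance check helper used by generators:
// smallest pairwise distance between rows of A and rows of B
// (optionally skipping pairs whose index difference is < min_sep when the
// matrices are the same chain).
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix A, NumericMatrix B, int offset,
                         int min_sep) {
  int n = A.nrow(), m = B.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int sep = (j + offset) - i;
      if (sep < 0) sep = -sep;
      if (sep < min_sep) continue;
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  }
  return best;
}
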