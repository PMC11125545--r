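// Kinetic Monte Carlo core for TFP-driven twitching motility.
//
// Units throughout: lengths in micrometres, forces in pN, energies in
// pN*um, times in seconds.  The surface is the plane z = 0 with z up.
// Body frame: e1 points from the trailing to the leading (piliated) pole.
// All randomness goes through R's RNG so that set.seed() in R makes every
// entry point reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const double DELTA_DEFAULT = 0.004; // pilus discretisation step (um)

// ---------------------------------------------------------------- vectors

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3& a) { return std::sqrt(dot(a, a)); }

// Rotation matrix stored row-major; columns are the body axes in world
// coordinates, so world = R * body.
struct M3 {
  double m[9];
  M3() { std::memset(m, 0, sizeof(m)); m[0] = m[4] = m[8] = 1.0; }
};
static inline V3 mul(const M3& R, const V3& v) {
  return V3(R.m[0] * v.x + R.m[1] * v.y + R.m[2] * v.z,
            R.m[3] * v.x + R.m[4] * v.y + R.m[5] * v.z,
            R.m[6] * v.x + R.m[7] * v.y + R.m[8] * v.z);
}
static M3 matmul(const M3& A, const M3& B) {
  M3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A.m[3 * i + k] * B.m[3 * k + j];
      C.m[3 * i + j] = s;
    }
  return C;
}
// Rodrigues rotation about world vector w (angle = |w|).
static M3 rodrigues(const V3& w) {
  double th = norm3(w);
  M3 R;
  if (th < 1e-14) return R;
  V3 k = (1.0 / th) * w;
  double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  R.m[0] = c + k.x * k.x * v;       R.m[1] = k.x * k.y * v - k.z * s; R.m[2] = k.x * k.z * v + k.y * s;
  R.m[3] = k.y * k.x * v + k.z * s; R.m[4] = c + k.y * k.y * v;       R.m[5] = k.y * k.z * v - k.x * s;
  R.m[6] = k.z * k.x * v - k.y * s; R.m[7] = k.z * k.y * v + k.x * s; R.m[8] = c + k.z * k.z * v;
  return R;
}
// Gram-Schmidt re-orthonormalisation (drift control after many updates).
static void reorthonormalise(M3& R) {
  V3 c0(R.m[0], R.m[3], R.m[6]), c1(R.m[1], R.m[4], R.m[7]);
  double n0 = norm3(c0); c0 = (1.0 / n0) * c0;
  c1 = c1 - dot(c1, c0) * c0;
  double n1 = norm3(c1); c1 = (1.0 / n1) * c1;
  V3 c2 = cross(c0, c1);
  R.m[0] = c0.x; R.m[3] = c0.y; R.m[6] = c0.z;
  R.m[1] = c1.x; R.m[4] = c1.y; R.m[7] = c1.z;
  R.m[2] = c2.x; R.m[5] = c2.y; R.m[8] = c2.z;
}

// ---------------------------------------------------------------- energy

struct Pot {
  int kind;       // 0 = repulsive, 1 = attractive well
  double eps;     // well depth (pN um)
  double range;   // well width (um)
  double kwall;   // wall stiffness (pN / um)
};

// Site potential as a function of the cap--surface gap, plus derivative.
static double site_potential(double gap, const Pot& p, double* dU) {
  double U = 0, d = 0;
  if (gap < 0) {
    U += 0.5 * p.kwall * gap * gap;
    d += p.kwall * gap;
    if (p.kind == 1) U -= p.eps; // well floor extends under the wall
  } else if (p.kind == 1 && gap < p.range) {
    double q = gap / p.range;
    U -= p.eps * (1.0 - q * q);
    d += 2.0 * p.eps * gap / (p.range * p.range);
  }
  if (dU) *dU = d;
  return U;
}

struct BoundPilus {
  V3 da;       // anchor offset from body centre, body frame
  V3 rb;       // surface attachment point, world frame
  double leq;  // equilibrium contour length
};

struct Pose {
  V3 c;
  M3 R;
};

// Total energy with gradient wrt (translation, world-frame rotation about
// the centre).  g[0..2] = dE/dc, g[3..5] = torque-like dE/dw.
static double energy_grad(const Pose& P, const std::vector<BoundPilus>& pili,
                          const Pot& pot, double body_r, double body_l,
                          double Emod, double* g,
                          double* e_surf_out = 0, double* e_pili_out = 0) {
  V3 axis(P.R.m[0], P.R.m[3], P.R.m[6]);
  double E = 0, e_surf = 0, e_pili = 0;
  if (g) for (int i = 0; i < 6; ++i) g[i] = 0;
  for (int s = -1; s <= 1; s += 2) {
    V3 p = P.c + (s * body_l / 2.0) * axis;
    double dU;
    double U = site_potential(p.z - body_r, pot, &dU);
    e_surf += U;
    if (g) {
      V3 f(0, 0, dU); // dE/dp
      g[0] += f.x; g[1] += f.y; g[2] += f.z;
      V3 tq = cross(p - P.c, f);
      g[3] += tq.x; g[4] += tq.y; g[5] += tq.z;
    }
  }
  for (size_t i = 0; i < pili.size(); ++i) {
    V3 ra = P.c + mul(P.R, pili[i].da);
    V3 dvec = ra - pili[i].rb;
    double d = norm3(dvec);
    double ext = d - pili[i].leq;
    if (ext > 0 && pili[i].leq > 0) {
      e_pili += 0.5 * Emod * ext * ext / pili[i].leq;
      if (g && d > 1e-14) {
        double tension = Emod * ext / pili[i].leq;
        V3 f = (tension / d) * dvec;
        g[0] += f.x; g[1] += f.y; g[2] += f.z;
        V3 tq = cross(ra - P.c, f);
        g[3] += tq.x; g[4] += tq.y; g[5] += tq.z;
      }
    }
  }
  E = e_surf + e_pili;
  if (e_surf_out) *e_surf_out = e_surf;
  if (e_pili_out) *e_pili_out = e_pili;
  return E;
}

// Solve the symmetric 6x6 system A x = b by Gaussian elimination with
// partial pivoting; returns false if (numerically) singular.
static bool solve6(double A[36], double b[6], double x[6]) {
  int piv[6];
  for (int i = 0; i < 6; ++i) piv[i] = i;
  for (int k = 0; k < 6; ++k) {
    int imax = k;
    double amax = std::fabs(A[6 * k + k]);
    for (int i = k + 1; i < 6; ++i) {
      double a = std::fabs(A[6 * i + k]);
      if (a > amax) { amax = a; imax = i; }
    }
    if (amax < 1e-300) return false;
    if (imax != k) {
      for (int j = 0; j < 6; ++j) std::swap(A[6 * k + j], A[6 * imax + j]);
      std::swap(b[k], b[imax]);
    }
    for (int i = k + 1; i < 6; ++i) {
      double f = A[6 * i + k] / A[6 * k + k];
      for (int j = k; j < 6; ++j) A[6 * i + j] -= f * A[6 * k + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = 5; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < 6; ++j) s -= A[6 * i + j] * x[j];
    x[i] = s / A[6 * i + i];
  }
  return true;
}

// Rigid-body relaxation: damped Newton on the preconditioned coordinates
// u = (dc, L dw) (L = l/2 makes the rotational block commensurate with
// translation), with the Hessian from central differences of the
// analytic gradient and Levenberg damping to keep every step a descent
// step.  Monotone in energy; re-based at the current pose every
// iteration; stops when the preconditioned gradient inf-norm drops
// below tol.
struct RelaxResult {
  int iterations;
  bool converged;
  double energy;
  double gnorm;
  double used; // relaxation time spent (s; only meaningful when gamma > 0)
};

static void apply_step(Pose& P, const double* u, double L) {
  P.c = P.c + V3(u[0], u[1], u[2]);
  V3 w(u[3] / L, u[4] / L, u[5] / L);
  P.R = matmul(rodrigues(w), P.R);
  reorthonormalise(P.R);
}

// With gamma > 0 the pose follows an overdamped quasi-static descent:
// the body moves toward mechanical equilibrium at speed |F|/gamma (F =
// the preconditioned force norm), and the call stops once `tbudget`
// seconds of that motion have been spent.  Dissipation is not modelled
// as an explicit force; the mobility 1/gamma is calibrated so that a
// stall-force load drags the body at the loaded retraction speed
// (gamma = f_stall / v_ret).  gamma = 0 gives strict local
// minimisation.
static RelaxResult relax_pose(Pose& P, const std::vector<BoundPilus>& pili,
                              const Pot& pot, double body_r, double body_l,
                              double Emod, double tol, int maxit,
                              double gamma = 0, double tbudget = 0,
                              double vcap = R_PosInf) {
  double L = body_l / 2.0;
  double tleft = (gamma > 0) ? tbudget : R_PosInf;
  double used = 0;
  double g[6];
  double E = energy_grad(P, pili, pot, body_r, body_l, Emod, g);
  RelaxResult res; res.iterations = 0; res.converged = false;
  double lambda = 1e-3;
  const double fd = 1e-6; // finite-difference step (um)
  for (int it = 0; it < maxit; ++it) {
    double gu[6];
    for (int i = 0; i < 3; ++i) { gu[i] = g[i]; gu[i + 3] = g[i + 3] / L; }
    double gmax = 0;
    for (int i = 0; i < 6; ++i) gmax = std::max(gmax, std::fabs(gu[i]));
    res.iterations = it;
    if (gmax < tol) { res.converged = true; break; }
    // Hessian of E(u) by central differences of the analytic gradient
    double H[36];
    for (int j = 0; j < 6; ++j) {
      double up[6] = {0, 0, 0, 0, 0, 0}, gp[6], gm[6];
      Pose Pp = P, Pm = P;
      up[j] = fd; apply_step(Pp, up, L);
      up[j] = -fd; apply_step(Pm, up, L);
      energy_grad(Pp, pili, pot, body_r, body_l, Emod, gp);
      energy_grad(Pm, pili, pot, body_r, body_l, Emod, gm);
      for (int i = 0; i < 3; ++i) {
        H[6 * i + j] = (gp[i] - gm[i]) / (2 * fd);
        H[6 * (i + 3) + j] = (gp[i + 3] - gm[i + 3]) / (L * 2 * fd);
      }
    }
    // symmetrise
    for (int i = 0; i < 6; ++i)
      for (int j = i + 1; j < 6; ++j) {
        double a = 0.5 * (H[6 * i + j] + H[6 * j + i]);
        H[6 * i + j] = H[6 * j + i] = a;
      }
    double hscale = 0;
    for (int i = 0; i < 6; ++i) hscale = std::max(hscale, std::fabs(H[7 * i]));
    if (hscale <= 0) hscale = 1;
    // Levenberg loop: damp until the step decreases the energy
    bool accepted = false;
    for (int trial = 0; trial < 30; ++trial) {
      double A[36], b[6], du[6];
      std::memcpy(A, H, sizeof(A));
      for (int i = 0; i < 6; ++i) {
        A[7 * i] += lambda * hscale;
        b[i] = -gu[i];
      }
      if (!solve6(A, b, du)) { lambda *= 10; continue; }
      double sn = 0;
      for (int i = 0; i < 6; ++i) sn += du[i] * du[i];
      sn = std::sqrt(sn);
      // trust region, and the overdamped displacement allowance for the
      // remaining time at the current force: |du| <= (|g|/gamma) * tleft
      double gn = 0;
      for (int i = 0; i < 6; ++i) gn += gu[i] * gu[i];
      gn = std::sqrt(gn);
      double lim = 0.2;
      double speed = gn / gamma;
      if (speed > vcap) speed = vcap;
      if (gamma > 0) lim = std::min(lim, speed * tleft);
      if (sn > lim) {
        for (int i = 0; i < 6; ++i) du[i] *= lim / sn;
        sn = lim;
      }
      Pose Pt = P;
      apply_step(Pt, du, L);
      double gt[6];
      double Et = energy_grad(Pt, pili, pot, body_r, body_l, Emod, gt);
      double gtmax = 0;
      for (int i = 0; i < 3; ++i) {
        gtmax = std::max(gtmax, std::fabs(gt[i]));
        gtmax = std::max(gtmax, std::fabs(gt[i + 3]) / L);
      }
      // accept on energy descent, or -- when the energy difference is
      // below floating-point resolution -- on gradient descent (pure
      // Newton refinement near the minimum)
      bool ok = (Et < E) ||
        (Et <= E + 1e-12 * (std::fabs(E) + 1e-12) && gtmax < gmax);
      if (ok) {
        P = Pt;
        E = Et;
        std::memcpy(g, gt, sizeof(gt));
        lambda = std::max(lambda / 5, 1e-9);
        if (gamma > 0 && gn > 0) { tleft -= sn / speed; used += sn / speed; }
        accepted = true;
        break;
      }
      lambda *= 10;
      if (lambda > 1e12) break;
    }
    if (!accepted) break; // no descent direction found at extreme damping
    if (tleft <= 1e-12) { res.converged = true; break; } // time budget spent
  }
  double gmax = 0;
  for (int i = 0; i < 3; ++i) {
    gmax = std::max(gmax, std::fabs(g[i]));
    gmax = std::max(gmax, std::fabs(g[i + 3]) / L);
  }
  res.energy = E;
  res.gnorm = gmax;
  res.used = used;
  return res;
}

// ------------------------------------------------------- directional draws

// Draw cos(theta) for a von Mises-Fisher distribution about the pole axis
// via inverse-CDF; azimuth uniform.
static inline double vmf_costheta(double kappa) {
  double u = unif_rand();
  // t = 1 + log(u + (1-u) e^{-2k}) / k, numerically safe for large kappa
  double e2k = std::exp(-2.0 * kappa);
  return 1.0 + std::log(u + (1.0 - u) * e2k) / kappa;
}

// Anchor placement on the spherocylinder: vMF polar angles below pi/4 stay
// on the leading cap; angles in [pi/4, pi/2] are mapped linearly onto the
// near half of the cylindrical wall; the back hemisphere is mirrored onto
// the same construction.
struct Anchor {
  V3 da;   // body-frame offset from the centre
  V3 na;   // outward normal, body frame
  bool on_cap;
};
static Anchor sample_anchor_bodyframe(double kappa, double body_l, double body_r) {
  double ct = vmf_costheta(kappa);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double theta = std::acos(ct);
  double psi = 2.0 * M_PI * unif_rand();
  Anchor a;
  double cp = std::cos(psi), sp = std::sin(psi);
  // the vMF draw is the pilus growth direction; the anchor site is that
  // direction transported onto the spherocylinder surface.  Back-
  // hemisphere draws keep their (backward-pointing) direction but their
  // anchor is constructed from the mirrored polar angle, so all pili
  // originate on the leading half of the body.
  // the vMF draw is also the filament's launch direction; the anchor
  // site is constructed from the mirrored polar angle so that all pili
  // originate on the leading half of the body
  V3 dir(std::cos(theta), std::sin(theta) * cp, std::sin(theta) * sp);
  double thm = (theta > M_PI / 2.0) ? M_PI - theta : theta;
  if (thm <= M_PI / 4.0) {
    // spherical cap about the leading pole (cap centre at +l/2 e1)
    V3 rad(std::cos(thm), std::sin(thm) * cp, std::sin(thm) * sp);
    a.da = V3(body_l / 2.0, 0, 0) + body_r * rad;
    a.on_cap = true;
  } else {
    // g(theta): [pi/4, pi/2] -> [pi/4, pi/4 + l/2]; offset along the wall
    double s = (thm - M_PI / 4.0) * (body_l / 2.0) / (M_PI / 4.0);
    a.da = V3(body_l / 2.0 - s, body_r * cp, body_r * sp);
    a.on_cap = false;
  }
  a.na = dir;
  return a;
}

// Rotate unit tangent t by polar angle th (about a uniform azimuth).
static V3 bend_tangent(const V3& t, double th) {
  // orthonormal frame (t, u, v)
  V3 ref = (std::fabs(t.x) < 0.9) ? V3(1, 0, 0) : V3(0, 1, 0);
  V3 u = cross(t, ref);
  double nu = norm3(u);
  if (nu < 1e-12) { u = V3(0, 0, 1); nu = 1; }
  u = (1.0 / nu) * u;
  V3 v = cross(t, u);
  double psi = 2.0 * M_PI * unif_rand();
  V3 w = std::cos(th) * t + std::sin(th) * (std::cos(psi) * u + std::sin(psi) * v);
  double nw = norm3(w);
  return (1.0 / nw) * w;
}

// One worm-like-chain bend angle: harmonic Boltzmann weight with the
// spherical sin(theta) measure, i.e. a Rayleigh draw with <theta^2> =
// 2 delta / L_p, matching the 3-D tangent correlation exp(-s/L_p).
static inline double wlc_angle(double Lp, double delta) {
  double sigma2 = delta / Lp;
  double u = unif_rand();
  if (u < 1e-300) u = 1e-300;
  return std::sqrt(-2.0 * sigma2 * std::log(u));
}

// Uniform direction on the outward hemisphere about n (|n| = 1).
static V3 hemisphere_dir(const V3& n) {
  double ct = unif_rand();               // cos(angle from n) ~ U(0,1)
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ps = 2.0 * M_PI * unif_rand();
  V3 ref = (std::fabs(n.x) < 0.9) ? V3(1, 0, 0) : V3(0, 1, 0);
  V3 u = cross(n, ref);
  double nu = norm3(u);
  if (nu < 1e-12) { u = V3(0, 0, 1); nu = 1; }
  u = (1.0 / nu) * u;
  V3 v = cross(n, u);
  return ct * n + st * (std::cos(ps) * u + std::sin(ps) * v);
}

// Sample a fresh chain of nseg segments from the anchor.  The filament
// pivots freely at its anchor: the first tangent is drawn uniformly on
// the outward hemisphere about the surface normal n0 (set free_pivot =
// false to clamp it along n0); subsequent tangents follow the WLC
// bending weight.  `block` > 1 draws the tangent process at a coarser
// arc-length resolution (block*delta) and lays delta-spaced nodes along
// straight sub-blocks -- exact for the harmonic bending model in the
// small-angle aggregation limit, and an order of magnitude cheaper for
// long chains.
static void sample_chain(std::vector<V3>& rel, int nseg, const V3& n0,
                         double Lp, double delta, bool free_pivot = true,
                         int block = 1) {
  rel.clear();
  rel.reserve(nseg);
  V3 t = free_pivot ? hemisphere_dir(n0) : n0;
  V3 p(0, 0, 0);
  if (block <= 1) {
    for (int i = 0; i < nseg; ++i) {
      if (i > 0) t = bend_tangent(t, wlc_angle(Lp, delta));
      p = p + delta * t;
      rel.push_back(p);
    }
    return;
  }
  int done = 0;
  while (done < nseg) {
    int n = std::min(block, nseg - done);
    if (done > 0) t = bend_tangent(t, wlc_angle(Lp, n * delta));
    for (int i = 0; i < n; ++i) {
      p = p + delta * t;
      rel.push_back(p);
    }
    done += n;
  }
}

// ------------------------------------------------------------ R interfaces

// [[Rcpp::export(name = ".cpp_vmf_costheta")]]
NumericVector cpp_vmf_costheta(int n, double kappa) {
  if (kappa <= 0) stop("kappa must be > 0");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vmf_costheta(kappa);
  return out;
}

// [[Rcpp::export(name = ".cpp_sample_anchor")]]
NumericMatrix cpp_sample_anchor(int n, double kappa, double body_l, double body_r) {
  if (kappa <= 0) stop("kappa must be > 0");
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    Anchor a = sample_anchor_bodyframe(kappa, body_l, body_r);
    out(i, 0) = a.da.x; out(i, 1) = a.da.y; out(i, 2) = a.da.z;
    out(i, 3) = a.na.x; out(i, 4) = a.na.y; out(i, 5) = a.na.z;
    out(i, 6) = a.on_cap ? 1.0 : 0.0;
  }
  colnames(out) = CharacterVector::create("da_x", "da_y", "da_z",
                                          "na_x", "na_y", "na_z", "on_cap");
  return out;
}

// [[Rcpp::export(name = ".cpp_sample_chain")]]
NumericMatrix cpp_sample_chain(int nseg, NumericVector normal, double Lp,
                               double delta, bool free_pivot) {
  std::vector<V3> rel;
  V3 n0(normal[0], normal[1], normal[2]);
  double nn = norm3(n0);
  n0 = (1.0 / nn) * n0;
  sample_chain(rel, nseg, n0, Lp, delta, free_pivot);
  NumericMatrix out(nseg, 3);
  for (int i = 0; i < nseg; ++i) {
    out(i, 0) = rel[i].x; out(i, 1) = rel[i].y; out(i, 2) = rel[i].z;
  }
  return out;
}

static Pose pose_from_args(NumericVector centre, NumericMatrix Rm) {
  Pose P;
  P.c = V3(centre[0], centre[1], centre[2]);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) P.R.m[3 * i + j] = Rm(i, j);
  return P;
}
static std::vector<BoundPilus> pili_from_matrix(Nullable<NumericMatrix> pm) {
  std::vector<BoundPilus> pili;
  if (pm.isNotNull()) {
    NumericMatrix m(pm);
    for (int i = 0; i < m.nrow(); ++i) {
      BoundPilus b;
      b.da = V3(m(i, 0), m(i, 1), m(i, 2));
      b.rb = V3(m(i, 3), m(i, 4), m(i, 5));
      b.leq = m(i, 6);
      pili.push_back(b);
    }
  }
  return pili;
}
static Pot pot_from_list(List pot) {
  Pot p;
  p.kind = as<int>(pot["kind"]);
  p.eps = as<double>(pot["epsilon"]);
  p.range = as<double>(pot["range"]);
  p.kwall = as<double>(pot["wall_stiffness"]);
  return p;
}

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(NumericVector centre, NumericMatrix Rm,
                Nullable<NumericMatrix> pili_m, List pot,
                double body_r, double body_l, double Emod) {
  Pose P = pose_from_args(centre, Rm);
  std::vector<BoundPilus> pili = pili_from_matrix(pili_m);
  Pot p = pot_from_list(pot);
  double es, ep;
  double g[6];
  double E = energy_grad(P, pili, p, body_r, body_l, Emod, g, &es, &ep);
  return List::create(_["surface"] = es, _["pili"] = ep, _["total"] = E,
                      _["gradient"] = NumericVector::create(g[0], g[1], g[2], g[3], g[4], g[5]));
}

// [[Rcpp::export(name = ".cpp_relax")]]
List cpp_relax(NumericVector centre, NumericMatrix Rm,
               Nullable<NumericMatrix> pili_m, List pot,
               double body_r, double body_l, double Emod,
               double tol, int maxit) {
  Pose P = pose_from_args(centre, Rm);
  std::vector<BoundPilus> pili = pili_from_matrix(pili_m);
  Pot p = pot_from_list(pot);
  RelaxResult r = relax_pose(P, pili, p, body_r, body_l, Emod, tol, maxit);
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = P.R.m[3 * i + j];
  return List::create(
      _["center"] = NumericVector::create(P.c.x, P.c.y, P.c.z),
      _["rotation"] = Rout, _["energy"] = r.energy,
      _["grad_norm"] = r.gnorm, _["iterations"] = r.iterations,
      _["converged"] = r.converged);
}

// ------------------------------------------------------------- KMC engine

struct Pilus {
  V3 da, na;            // anchor offset / launch direction, body frame
  // Free-chain node positions relative to the anchor, world frame: a
  // frozen thermal shape is tethered at the anchor (it follows the
  // anchor's translation but does not co-rotate with the body between
  // resamplings).
  std::vector<V3> rel;
  int nseg;             // l_eq = nseg * delta
  int motor;            // 0 ext, 1 passive(after ext), 2 ret, 3 passive(after ret),
                        // 4 bound-delay, 5 bound-retracting
  bool bound;
  V3 rb;                // world attachment point (bound only)
  bool stalled;
  // diagnostics
  int id;
  double t_spawn;
  bool ever_bound;
  double dx;            // body displacement attributed to own retraction events
  double max_len;
};

struct PilusRecord {
  int id;
  double t_spawn, t_end;
  bool ever_bound;
  double dx, max_len;
};

struct Engine {
  // parameters
  double body_r, body_l, delta;
  double kappa, k_spawn, k_resample;
  double k_ext_off, k_ret_on, k_ret_off, k_ext_on;
  double v_ext, v_ret, tau_dwell, tau_delay;
  double Lp, Emod, f_stall;
  Pot pot;
  double relax_tol;
  int relax_maxit;
  double relax_tmax;   // maximum stored relaxation time credit (s)
  double relax_credit; // elapsed time since the pose last tracked equilibrium
  double gamma() const { return f_stall / v_ret; }
  int chain_block() const {
    int b = (int)std::floor(Lp / (25.0 * delta));
    if (b < 1) b = 1;
    if (b > 10) b = 10;
    return b;
  }
  bool enable_binding;
  bool free_pivot;    // chain launch: free anchor pivot vs clamped along the draw

  Pose P;
  std::vector<Pilus> pili;
  double t;
  int next_id;
  long n_events, n_relax;
  int n_relax_fail;
  double disp_ret, disp_other; // leading-pole path split by relax trigger
  long nb_spawn, nb_ext, nb_resample, nb_move; // binding-channel counters
  long nodes_sampled, relax_grad_evals;
  std::vector<PilusRecord> records;

  double k_detach() const { return (tau_dwell > 0 && std::isfinite(tau_dwell)) ? 1.0 / tau_dwell : 0.0; }
  double ext_step_rate() const { return v_ext / delta; }
  double ret_step_rate() const { return v_ret / delta; }

  V3 axis() const { return V3(P.R.m[0], P.R.m[3], P.R.m[6]); }
  V3 lead_pole() const { return P.c + (body_l / 2.0) * axis(); }
  V3 trail_pole() const { return P.c - (body_l / 2.0) * axis(); }
  V3 anchor_world(const Pilus& p) const { return P.c + mul(P.R, p.da); }

  double rab(const Pilus& p) const { return norm3(anchor_world(p) - p.rb); }

  // Stall check: tension builds up in a restrained pilus until it
  // exceeds the stall force, at which point retraction stops.  An
  // unrestrained bound pilus keeps near-zero tension (relaxation tracks
  // the shrinking rest length) and retracts all the way to dissolution.
  bool retraction_blocked(const Pilus& p) const {
    if (!p.bound) return false;
    double leq = p.nseg * delta;
    double ext = rab(p) - leq;
    if (ext <= 0) return false;
    return Emod * ext / leq > f_stall;
  }

  void update_stalls() {
    for (size_t i = 0; i < pili.size(); ++i)
      if (pili[i].bound) pili[i].stalled = retraction_blocked(pili[i]);
  }

  // Tip--surface contact test for a free chain at the current pose:
  // pili adhere at their tips only, so a chain binds exactly when its
  // tip node lies below the surface.  The attachment point is where the
  // last segment crosses z = 0 (or the tip's surface projection if the
  // penultimate node is below as well).
  int chain_hit(const Pilus& p, V3* rb_out) const {
    if (!enable_binding || p.bound || p.nseg == 0) return 0;
    V3 raw = anchor_world(p);
    if (raw.z - p.nseg * delta > 0) return 0; // reach prune
    const V3& a = p.rel[p.nseg - 1];
    double ztip = raw.z + a.z;
    if (ztip >= 0) return 0;
    if (rb_out) {
      V3 cur = raw + a;
      double zp;
      V3 prev;
      if (p.nseg >= 2) {
        const V3& b = p.rel[p.nseg - 2];
        zp = raw.z + b.z;
        prev = raw + b;
      } else {
        zp = raw.z;
        prev = raw;
      }
      V3 hit = cur;
      if (zp >= 0) {
        double f = zp / (zp - ztip);
        hit = prev + f * (cur - prev);
      }
      hit.z = 0;
      *rb_out = hit;
    }
    return p.nseg;
  }

  void bind(Pilus& p, const V3& rb) {
    p.bound = true;
    p.rb = rb;
    p.rel.clear();
    p.ever_bound = true;
    p.motor = (tau_delay > 0) ? 4 : 5;
  }

  void finish_pilus(const Pilus& p, double tend) {
    PilusRecord r;
    r.id = p.id; r.t_spawn = p.t_spawn; r.t_end = tend;
    r.ever_bound = p.ever_bound; r.dx = p.dx; r.max_len = p.max_len;
    records.push_back(r);
  }

  void dissolve(size_t idx) {
    finish_pilus(pili[idx], t);
    pili.erase(pili.begin() + idx);
  }

  // Relax the body, then rebind any free chain that the move pushed through
  // the surface; repeat until stable.  `who` (or -1) gets credited with the
  // leading-pole displacement of the first relaxation.  Retraction-driven
  // relaxations are limited by the dissipation budget (the body tracks
  // equilibrium at the loaded retraction speed); detachment releases the
  // stored elastic energy in one uncapped slingshot relaxation.
  void relax_and_rebind(int who_id, bool full = false) {
    for (int pass = 0; pass < 12; ++pass) {
      std::vector<BoundPilus> bp;
      for (size_t i = 0; i < pili.size(); ++i)
        if (pili[i].bound) {
          BoundPilus b;
          b.da = pili[i].da; b.rb = pili[i].rb; b.leq = pili[i].nseg * delta;
          bp.push_back(b);
        }
      V3 lead0 = lead_pole();
      RelaxResult rr = relax_pose(P, bp, pot, body_r, body_l, Emod, relax_tol,
                                  relax_maxit, full ? 0.0 : gamma(),
                                  relax_credit, v_ret);
      if (!full) {
        relax_credit -= rr.used;
        if (relax_credit < 0) relax_credit = 0;
      }
      ++n_relax;
      if (!rr.converged) ++n_relax_fail;
      {
        V3 d = lead_pole() - lead0;
        double dxy = std::sqrt(d.x * d.x + d.y * d.y);
        if (pass == 0 && who_id >= 0) {
          disp_ret += dxy;
          for (size_t i = 0; i < pili.size(); ++i)
            if (pili[i].id == who_id) { pili[i].dx += dxy; break; }
        } else {
          disp_other += dxy;
        }
      }
      bool any = false;
      for (size_t i = 0; i < pili.size(); ++i) {
        if (pili[i].bound) continue;
        V3 rb;
        if (chain_hit(pili[i], &rb)) { bind(pili[i], rb); ++nb_move; any = true; }
      }
      if (!any) break;
    }
    update_stalls();
  }

  void spawn() {
    Pilus p;
    Anchor a = sample_anchor_bodyframe(kappa, body_l, body_r);
    p.da = a.da; p.na = a.na;
    p.nseg = 1;
    p.rel.assign(1, delta * (free_pivot ? hemisphere_dir(mul(P.R, a.na)) : mul(P.R, a.na)));
    p.motor = 0;
    p.bound = false;
    p.stalled = false;
    p.id = next_id++;
    p.t_spawn = t;
    p.ever_bound = false;
    p.dx = 0;
    p.max_len = delta;
    V3 rb;
    pili.push_back(p);
    Pilus& ref = pili.back();
    if (chain_hit(ref, &rb)) {
      bind(ref, rb);
      ++nb_spawn;
      relax_and_rebind(-1);
    }
  }

  void apply_free_event(size_t i, int which) {
    Pilus& p = pili[i];
    switch (which) {
      case 0: { // resample chain (world frame, launch direction R na)
        // The thermal ensemble of a chain above the impenetrable surface
        // carries no weight on wall-overlapping configurations: redraw
        // intersecting samples.  A chain that cannot avoid the wall is
        // trapped against it and binds.
        V3 n0 = mul(P.R, p.na);
        V3 rb;
        bool hit = true;
        for (int tries = 0; tries < 4; ++tries) {
          sample_chain(p.rel, p.nseg, n0, Lp, delta, free_pivot, chain_block());
          nodes_sampled += p.nseg / chain_block();
          if (!chain_hit(p, &rb)) { hit = false; break; }
        }
        if (hit) { bind(p, rb); ++nb_resample; relax_and_rebind(-1); }
        break;
      }
      case 1: { // extension step
        V3 tlast = (p.nseg >= 2)
                       ? (1.0 / delta) * (p.rel[p.nseg - 1] - p.rel[p.nseg - 2])
                       : mul(P.R, p.na);
        V3 tnew = bend_tangent(tlast, wlc_angle(Lp, delta));
        p.rel.push_back(p.rel[p.nseg - 1] + delta * tnew);
        p.nseg++;
        p.max_len = std::max(p.max_len, p.nseg * delta);
        // only the new node can newly cross the surface
        V3 raw = anchor_world(p);
        const V3& a = p.rel[p.nseg - 1];
        double zi = raw.z + a.z;
        if (enable_binding && zi < 0) {
          const V3& b = p.rel[p.nseg - 2];
          double zp = raw.z + b.z;
          V3 prev = raw + b, cur = raw + a;
          double f = (zp >= 0) ? zp / (zp - zi) : 0.0;
          V3 hit = prev + f * (cur - prev);
          hit.z = 0;
          bind(p, hit);
          ++nb_ext;
          relax_and_rebind(-1);
        }
        break;
      }
      case 2: { // free retraction step
        p.nseg--;
        p.rel.pop_back();
        if (p.nseg == 0) dissolve(i);
        break;
      }
      case 3: p.motor = 1; break; // ext motor off
      case 4: p.motor = 2; break; // ret motor on
      case 5: p.motor = 3; break; // ret motor off
      case 6: p.motor = 0; break; // ext motor on
    }
  }

  void detach(size_t i) {
    Pilus& p = pili[i];
    p.bound = false;
    // surface-sensing limit: the bound pilus was retracting, and the
    // retraction motor stays attached on release
    p.motor = 2;
    p.nseg--;
    if (p.nseg == 0) {
      dissolve(i);
      relax_and_rebind(-1, true);
      return;
    }
    sample_chain(p.rel, p.nseg, mul(P.R, p.na), Lp, delta, free_pivot,
                 chain_block());
    while (chain_hit(p, 0)) {
      p.nseg--;
      if (p.nseg == 0) break;
      p.rel.pop_back();
    }
    if (p.nseg == 0) dissolve(i);
    // losing an attachment releases the stored elastic energy as one
    // impulsive slingshot: the remaining springs snap the body to the
    // new equilibrium much faster than the creep timescale
    relax_and_rebind(-1, true);
  }

  void bound_retract(size_t i) {
    Pilus& p = pili[i];
    p.nseg--;
    int id = p.id;
    if (p.nseg == 0) { // retracted to zero while bound: dissolved immediately
      dissolve(i);
      relax_and_rebind(-1, true);
      return;
    }
    // batch micro-relaxations: with less than half a discretisation step
    // of displacement allowance available, accrue credit and only update
    // the stall flags; the pose catches up once the quantum is worth
    // moving (the chains cannot newly intersect while the body is still)
    if (relax_credit < 0.5 * delta) {
      update_stalls();
      return;
    }
    relax_and_rebind(id);
  }

  // Per-pilus event rates, mirroring event_rates() at the R level.
  double pilus_rate(const Pilus& p) const {
    if (p.bound) {
      double r = k_detach();
      if (p.motor == 4) r += 1.0 / tau_delay;
      if (p.motor == 5 && !p.stalled) r += ret_step_rate();
      return r;
    }
    double r = k_resample;
    switch (p.motor) {
      case 0: r += k_ext_off + ext_step_rate(); break;
      case 1: r += k_ret_on; break;
      case 2: r += k_ret_off + ret_step_rate(); break;
      case 3: r += k_ext_on; break;
    }
    return r;
  }

  double total_rate() const {
    double total = k_spawn;
    for (size_t i = 0; i < pili.size(); ++i) total += pilus_rate(pili[i]);
    return total;
  }

  // Select and apply one event (time has already been advanced).
  void apply_event(double total) {
    double u = unif_rand() * total;
    ++n_events;
    if (u < k_spawn) { spawn(); return; }
    u -= k_spawn;
    for (size_t i = 0; i < pili.size(); ++i) {
      double r = pilus_rate(pili[i]);
      if (u >= r) { u -= r; continue; }
      Pilus& p = pili[i];
      if (p.bound) {
        if (u < k_detach()) { detach(i); return; }
        u -= k_detach();
        if (p.motor == 4) {
          if (u < 1.0 / tau_delay) { p.motor = 5; return; }
          u -= 1.0 / tau_delay;
        }
        bound_retract(i);
        return;
      }
      if (u < k_resample) { apply_free_event(i, 0); return; }
      u -= k_resample;
      switch (p.motor) {
        case 0:
          if (u < k_ext_off) apply_free_event(i, 3);
          else apply_free_event(i, 1);
          return;
        case 1: apply_free_event(i, 4); return;
        case 2:
          if (u < k_ret_off) apply_free_event(i, 5);
          else apply_free_event(i, 2);
          return;
        case 3: apply_free_event(i, 6); return;
      }
      return;
    }
    // numerical fall-through: treat as spawn
    spawn();
  }
};

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List par) {
  Engine E;
  E.body_r = as<double>(par["r"]);
  E.body_l = as<double>(par["l"]);
  E.delta = as<double>(par["delta_step"]);
  E.kappa = as<double>(par["kappa"]);
  E.k_spawn = as<double>(par["k_spawn"]);
  E.k_resample = as<double>(par["k_resample"]);
  E.k_ext_off = as<double>(par["k_ext_off"]);
  E.k_ret_on = as<double>(par["k_ret_on"]);
  E.k_ret_off = as<double>(par["k_ret_off"]);
  E.k_ext_on = as<double>(par["k_ext_on"]);
  E.v_ext = as<double>(par["v_ext"]);
  E.v_ret = as<double>(par["v_ret"]);
  E.tau_dwell = as<double>(par["tau_dwell"]);
  E.tau_delay = as<double>(par["tau_delay"]);
  E.Lp = as<double>(par["L_p"]);
  E.Emod = as<double>(par["E"]);
  E.f_stall = as<double>(par["f_stall"]);
  E.pot = pot_from_list(par["surface"]);
  E.relax_tol = as<double>(par["relax_tol"]);
  E.relax_maxit = as<int>(par["relax_maxit"]);
  E.relax_tmax = par.containsElementNamed("relax_tmax") ? as<double>(par["relax_tmax"]) : 1.0;
  E.enable_binding = as<bool>(par["enable_binding"]);
  E.free_pivot = par.containsElementNamed("free_pivot") ? as<bool>(par["free_pivot"]) : false;
  double duration = as<double>(par["duration"]);
  double frame_dt = as<double>(par["frame_dt"]);
  double vis1 = 0.3, vis2 = 1.0;

  std::string mode = as<std::string>(par["mode"]);
  E.P = Pose();
  if (mode == "crawling") {
    E.P.c = V3(0, 0, E.body_r);
  } else {
    // walking: leading (piliated) pole down, axis = (0,0,-1)
    E.P.c = V3(0, 0, E.body_r + E.body_l / 2.0);
    M3 R;
    R.m[0] = 0; R.m[1] = 0; R.m[2] = 1;
    R.m[3] = 0; R.m[4] = 1; R.m[5] = 0;
    R.m[6] = -1; R.m[7] = 0; R.m[8] = 0;
    E.P.R = R;
  }
  if (par.containsElementNamed("init_center") && !Rf_isNull(par["init_center"])) {
    NumericVector c0 = par["init_center"];
    E.P.c = V3(c0[0], c0[1], c0[2]);
  }
  E.t = 0;
  E.next_id = 1;
  E.n_events = E.n_relax = 0;
  E.n_relax_fail = 0;
  E.disp_ret = E.disp_other = 0;
  E.nb_spawn = E.nb_ext = E.nb_resample = E.nb_move = 0;
  E.nodes_sampled = E.relax_grad_evals = 0;

  if (par.containsElementNamed("init_pili") && !Rf_isNull(par["init_pili"])) {
    NumericMatrix ip = par["init_pili"];
    // columns: da(3), na(3), nseg, bound, rb(3), motor
    for (int i = 0; i < ip.nrow(); ++i) {
      Pilus p;
      p.da = V3(ip(i, 0), ip(i, 1), ip(i, 2));
      p.na = V3(ip(i, 3), ip(i, 4), ip(i, 5));
      p.nseg = (int)ip(i, 6);
      p.bound = ip(i, 7) != 0;
      p.rb = V3(ip(i, 8), ip(i, 9), ip(i, 10));
      p.motor = (int)ip(i, 11);
      p.stalled = false;
      p.id = E.next_id++;
      p.t_spawn = 0;
      p.ever_bound = p.bound;
      p.dx = 0;
      p.max_len = p.nseg * E.delta;
      if (!p.bound) sample_chain(p.rel, p.nseg, mul(E.P.R, p.na), E.Lp, E.delta, E.free_pivot, E.chain_block());
      E.pili.push_back(p);
    }
    E.update_stalls();
  }

  int nframes = (int)std::floor(duration / frame_dt + 1e-9) + 1;
  NumericMatrix frames(nframes, 16);
  colnames(frames) = CharacterVector::create(
      "t", "x_lead", "y_lead", "z_lead", "x_trail", "y_trail", "z_trail",
      "bx", "by", "bz", "n_tfp", "n_bound", "n_taut", "n_vis03", "n_vis10",
      "n_stalled");
  int fi = 0;
  double next_frame = 0;

  auto record = [&](double ft) {
    if (fi >= nframes) return;
    V3 lp = E.lead_pole(), tp = E.trail_pole(), ax = E.axis();
    int nb = 0, nt = 0, nv1 = 0, nv2 = 0, nst = 0;
    for (size_t i = 0; i < E.pili.size(); ++i) {
      const Pilus& p = E.pili[i];
      double len = p.nseg * E.delta;
      if (len >= vis1) ++nv1;
      if (len >= vis2) ++nv2;
      if (p.bound) {
        ++nb;
        if (E.rab(p) >= len - E.delta) ++nt;
        if (p.stalled) ++nst;
      }
    }
    frames(fi, 0) = ft;
    frames(fi, 1) = lp.x; frames(fi, 2) = lp.y; frames(fi, 3) = lp.z;
    frames(fi, 4) = tp.x; frames(fi, 5) = tp.y; frames(fi, 6) = tp.z;
    frames(fi, 7) = ax.x; frames(fi, 8) = ax.y; frames(fi, 9) = ax.z;
    frames(fi, 10) = (double)E.pili.size();
    frames(fi, 11) = nb; frames(fi, 12) = nt;
    frames(fi, 13) = nv1; frames(fi, 14) = nv2;
    frames(fi, 15) = nst;
    ++fi;
  };

  // settle the initial pose into the surface potential (full minimisation:
  // this is initial-condition preparation, not dynamics)
  E.relax_credit = 0;
  E.relax_and_rebind(-1, true);
  long guard = 0;
  // The KMC state is piecewise constant between events: every frame time
  // inside a waiting interval is recorded with the pre-event state.  The
  // overdamped body creep, however, is continuous in time, so at every
  // frame boundary with bound pili present a budgeted catch-up
  // relaxation runs before the frame is recorded; without it a fully
  // stalled configuration (whose tension only relaxes through body
  // motion) could deadlock, since no events would ever fire.
  auto any_bound = [&]() {
    for (size_t i = 0; i < E.pili.size(); ++i)
      if (E.pili[i].bound) return true;
    return false;
  };
  while (E.t < duration && fi < nframes) {
    double total = E.total_rate();
    if (total <= 0 && !any_bound()) break; // truly frozen; frames filled below
    double dt = (total > 0) ? exp_rand() / total
                            : (next_frame - E.t + 1e-9);
    double tnew = E.t + dt;
    // the body tracks mechanical equilibrium at speed |F|/gamma, so each
    // waiting interval adds to the relaxation time credit (with a cap so
    // that long quiet stretches cannot bank unbounded catch-up motion)
    E.relax_credit = std::min(E.relax_credit + dt, E.relax_tmax);
    while (next_frame <= tnew && fi < nframes) {
      if (any_bound()) E.relax_and_rebind(-1);
      record(next_frame);
      next_frame += frame_dt;
    }
    E.t = tnew;
    if (tnew >= duration) break;
    if (total > 0) E.apply_event(total);
    if (++guard > 500000000L) break; // hard safety net
  }
  while (fi < nframes) {
    record(next_frame);
    next_frame += frame_dt;
  }

  // flush survivors into the per-pilus table with censored end times
  for (size_t i = 0; i < E.pili.size(); ++i) E.finish_pilus(E.pili[i], NA_REAL);

  NumericMatrix ptab(E.records.size(), 6);
  colnames(ptab) = CharacterVector::create("id", "t_spawn", "t_end",
                                           "ever_bound", "dx", "max_len");
  for (size_t i = 0; i < E.records.size(); ++i) {
    const PilusRecord& r = E.records[i];
    ptab(i, 0) = r.id; ptab(i, 1) = r.t_spawn; ptab(i, 2) = r.t_end;
    ptab(i, 3) = r.ever_bound ? 1 : 0; ptab(i, 4) = r.dx; ptab(i, 5) = r.max_len;
  }

  return List::create(_["frames"] = frames, _["pili"] = ptab,
                      _["n_events"] = (double)E.n_events,
                      _["n_relax"] = (double)E.n_relax,
                      _["n_relax_fail"] = E.n_relax_fail,
                      _["disp_ret"] = E.disp_ret,
                      _["disp_other"] = E.disp_other,
                      _["nodes_sampled"] = (double)E.nodes_sampled,
                      _["bind_channels"] = NumericVector::create(
                          _["spawn"] = (double)E.nb_spawn, _["ext"] = (double)E.nb_ext,
                          _["resample"] = (double)E.nb_resample, _["move"] = (double)E.nb_move));
}
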