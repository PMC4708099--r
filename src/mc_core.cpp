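// Core numerical kernels for the hierarchical natural-move Monte Carlo
// engine: pair-potential energy sums (full and incremental), rigid-body
// move application, cyclic-coordinate-descent chain closure, and the
// Metropolis loop under the periodic annealing schedule.
//
// Conventions: coordinates in nm, energies in units of k_B * T_ref,
// temperatures in Kelvin. All randomness comes from R's RNG so that
// set.seed() at the R level makes every run bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct FF {
  const double *E;   // [nt x nt x nb]
  int nt, nb;
  double bin_w, cutoff, cutoff2, s0, r0;
  int min_sep;
};

// scaled pair energy between beads a and b given squared distance pieces
static inline double pair_e(const FF &ff, int ti, int tj, double r2) {
  if (r2 >= ff.cutoff2) return 0.0;
  double r = std::sqrt(r2);
  int bin = (int)(r / ff.bin_w);
  if (bin >= ff.nb) return 0.0;
  double e = ff.E[ti + (size_t)ff.nt * tj + (size_t)ff.nt * ff.nt * bin];
  if (r < ff.r0) {
    double x = r / ff.r0;
    double x3 = x * x * x;
    e *= (ff.s0 + (1.0 - ff.s0) * x3 * x3);
  }
  return e;
}

static inline bool excluded(const FF &ff, int ci, int cj, int oi, int oj) {
  return ci == cj && std::abs(oi - oj) < ff.min_sep;
}

// pair class: 0 = intra-receptor, 1 = peptide-receptor, 2 = intra-peptide
static inline int pair_class(int gi, int gj) { return gi + gj; }

static FF make_ff(const NumericVector &energies, int nt, int nb, double bin_w,
                  double cutoff, int min_sep, double s0, double r0) {
  FF ff;
  ff.E = energies.begin();
  ff.nt = nt; ff.nb = nb;
  ff.bin_w = bin_w; ff.cutoff = cutoff; ff.cutoff2 = cutoff * cutoff;
  ff.s0 = s0; ff.r0 = r0; ff.min_sep = min_sep;
  return ff;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix coords, IntegerVector type,
                               IntegerVector chain, IntegerVector ord,
                               IntegerVector group, NumericVector energies,
                               int nt, int nb, double bin_w, double cutoff,
                               int min_sep, double s0, double r0) {
  FF ff = make_ff(energies, nt, nb, bin_w, cutoff, min_sep, s0, r0);
  int n = coords.nrow();
  double tot[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (excluded(ff, chain[i], chain[j], ord[i], ord[j])) continue;
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1), dz = zi - coords(j, 2);
      double e = pair_e(ff, type[i] - 1, type[j] - 1, dx * dx + dy * dy + dz * dz);
      tot[pair_class(group[i], group[j])] += e;
    }
  }
  return NumericVector::create(tot[0] + tot[1] + tot[2], tot[1], tot[0], tot[2]);
}

// energy over all pairs with at least one endpoint in `subset` (1-based)
static double subset_energy(const std::vector<double> &X, int n, const FF &ff,
                            const int *type, const int *chain, const int *ord,
                            const std::vector<char> &mask,
                            const std::vector<int> &subset0) {
  double tot = 0.0;
  for (size_t k = 0; k < subset0.size(); ++k) {
    int i = subset0[k];
    double xi = X[3 * i], yi = X[3 * i + 1], zi = X[3 * i + 2];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (mask[j] && j < i) continue; // count affected-affected pairs once
      if (excluded(ff, chain[i], chain[j], ord[i], ord[j])) continue;
      double dx = xi - X[3 * j], dy = yi - X[3 * j + 1], dz = zi - X[3 * j + 2];
      tot += pair_e(ff, type[i] - 1, type[j] - 1, dx * dx + dy * dy + dz * dz);
    }
  }
  return tot;
}

// [[Rcpp::export]]
double cpp_subset_energy(NumericMatrix coords, IntegerVector subset,
                         IntegerVector type, IntegerVector chain,
                         IntegerVector ord, NumericVector energies, int nt,
                         int nb, double bin_w, double cutoff, int min_sep,
                         double s0, double r0) {
  FF ff = make_ff(energies, nt, nb, bin_w, cutoff, min_sep, s0, r0);
  int n = coords.nrow();
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i) {
    X[3 * i] = coords(i, 0); X[3 * i + 1] = coords(i, 1); X[3 * i + 2] = coords(i, 2);
  }
  std::vector<char> mask(n, 0);
  std::vector<int> sub0(subset.size());
  for (int k = 0; k < subset.size(); ++k) { sub0[k] = subset[k] - 1; mask[sub0[k]] = 1; }
  return subset_energy(X, n, ff, type.begin(), chain.begin(), ord.begin(), mask, sub0);
}

// draw a symmetric rigid-body proposal using R's RNG:
// translation uniform in [-tmax, tmax]^3, axis uniform on the sphere
// (normalised Gaussian triple), angle uniform in [-rmax, rmax] degrees.
// [[Rcpp::export]]
NumericVector cpp_propose(double tmax, double rmax_deg) {
  NumericVector out(7);
  for (int d = 0; d < 3; ++d) out[d] = (2.0 * unif_rand() - 1.0) * tmax;
  double ax, ay, az, nrm;
  do {
    ax = norm_rand(); ay = norm_rand(); az = norm_rand();
    nrm = std::sqrt(ax * ax + ay * ay + az * az);
  } while (nrm < 1e-12);
  out[3] = ax / nrm; out[4] = ay / nrm; out[5] = az / nrm;
  out[6] = (2.0 * unif_rand() - 1.0) * rmax_deg;
  return out;
}

// rotate points (in place) about an axis line (point p, unit dir u) by angle
static void rotate_about(std::vector<double> &X, const std::vector<int> &idx0,
                         const double *p, const double *u, double theta) {
  double c = std::cos(theta), s = std::sin(theta);
  for (size_t k = 0; k < idx0.size(); ++k) {
    int i = idx0[k];
    double vx = X[3 * i] - p[0], vy = X[3 * i + 1] - p[1], vz = X[3 * i + 2] - p[2];
    double dot = vx * u[0] + vy * u[1] + vz * u[2];
    double cx = u[1] * vz - u[2] * vy, cy = u[2] * vx - u[0] * vz, cz = u[0] * vy - u[1] * vx;
    X[3 * i]     = p[0] + vx * c + cx * s + u[0] * dot * (1 - c);
    X[3 * i + 1] = p[1] + vy * c + cy * s + u[1] * dot * (1 - c);
    X[3 * i + 2] = p[2] + vz * c + cz * s + u[2] * dot * (1 - c);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_move(NumericMatrix coords, IntegerVector idx,
                             NumericVector pivot, NumericVector axis,
                             double angle_deg, NumericVector trans) {
  NumericMatrix out = clone(coords);
  int n = out.nrow();
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = out(i, d);
  std::vector<int> idx0(idx.size());
  for (int k = 0; k < idx.size(); ++k) idx0[k] = idx[k] - 1;
  double p[3] = {pivot[0], pivot[1], pivot[2]};
  double u[3] = {axis[0], axis[1], axis[2]};
  double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (nu > 1e-12) {
    u[0] /= nu; u[1] /= nu; u[2] /= nu;
    rotate_about(X, idx0, p, u, angle_deg * M_PI / 180.0);
  }
  for (size_t k = 0; k < idx0.size(); ++k)
    for (int d = 0; d < 3; ++d) X[3 * idx0[k] + d] += trans[d];
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = X[3 * i + d];
  return out;
}

static inline double dist3(const std::vector<double> &X, int i, int j) {
  double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
         dz = X[3 * i + 2] - X[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// One CCD axis update: choose the rotation angle about the axis line
// (through CA p, toward CA q) that brings |target - fixed| closest to d0.
// The swept point is `mob` (the zone CA adjacent to the break); beads in
// `rot` are rotated rigidly by the chosen angle.
static void ccd_axis(std::vector<double> &X, int p, int q, int mob, int fix,
                     double d0, const std::vector<int> &rot, double max_angle) {
  double u[3] = {X[3 * q] - X[3 * p], X[3 * q + 1] - X[3 * p + 1], X[3 * q + 2] - X[3 * p + 2]};
  double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (nu < 1e-12) return;
  u[0] /= nu; u[1] /= nu; u[2] /= nu;
  double P[3] = {X[3 * p], X[3 * p + 1], X[3 * p + 2]};
  // circle of the mobile CA about the axis
  double w[3] = {X[3 * mob] - P[0], X[3 * mob + 1] - P[1], X[3 * mob + 2] - P[2]};
  double along = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
  double C[3] = {P[0] + along * u[0], P[1] + along * u[1], P[2] + along * u[2]};
  double uv[3] = {X[3 * mob] - C[0], X[3 * mob + 1] - C[1], X[3 * mob + 2] - C[2]};
  double r2 = uv[0] * uv[0] + uv[1] * uv[1] + uv[2] * uv[2];
  if (r2 < 1e-16) return; // mobile point on the axis: no leverage
  double vv[3] = {u[1] * uv[2] - u[2] * uv[1], u[2] * uv[0] - u[0] * uv[2],
                  u[0] * uv[1] - u[1] * uv[0]};
  double F[3] = {X[3 * fix], X[3 * fix + 1], X[3 * fix + 2]};
  double g[3] = {C[0] - F[0], C[1] - F[1], C[2] - F[2]};
  double c0 = g[0] * g[0] + g[1] * g[1] + g[2] * g[2] + r2;
  double a = 2.0 * (g[0] * uv[0] + g[1] * uv[1] + g[2] * uv[2]);
  double b = 2.0 * (g[0] * vv[0] + g[1] * vv[1] + g[2] * vv[2]);
  // |mob(theta) - F|^2 = c0 + a cos(theta) + b sin(theta)
  double R = std::sqrt(a * a + b * b);
  double theta;
  double want = d0 * d0 - c0;
  double phi = std::atan2(b, a);
  if (R < 1e-14) return;
  if (std::fabs(want) <= R) {
    double dlt = std::acos(std::max(-1.0, std::min(1.0, want / R)));
    double t1 = phi + dlt, t2 = phi - dlt;
    // wrap to [-pi, pi] and take the smaller rotation
    auto wrap = [](double t) {
      while (t > M_PI) t -= 2 * M_PI;
      while (t < -M_PI) t += 2 * M_PI;
      return t;
    };
    t1 = wrap(t1); t2 = wrap(t2);
    theta = (std::fabs(t1) < std::fabs(t2)) ? t1 : t2;
  } else {
    theta = (want > 0) ? phi : phi + M_PI;
    while (theta > M_PI) theta -= 2 * M_PI;
    while (theta < -M_PI) theta += 2 * M_PI;
  }
  if (theta > max_angle) theta = max_angle;
  if (theta < -max_angle) theta = -max_angle;
  rotate_about(X, rot, P, u, theta);
}

struct BreakSpec {
  int u, v;              // CA beads adjacent to the gap: u in the zone, v in the moved region
  std::vector<int> zone; // all zone beads (rotated during closure)
  bool rigid;            // zone covers a whole terminal flank: close as a rigid hinge
  int far_ca;            // hinge pivot: CA at the flank's free end (rigid only)
  struct Axis { int p, q; std::vector<int> rot; };
  std::vector<Axis> axes;
};

static std::vector<BreakSpec> parse_breaks(List breaks) {
  std::vector<BreakSpec> out;
  for (int b = 0; b < breaks.size(); ++b) {
    List br = breaks[b];
    BreakSpec bs;
    bs.u = as<int>(br["u"]) - 1;
    bs.v = as<int>(br["v"]) - 1;
    bs.rigid = br.containsElementNamed("rigid") ? as<bool>(br["rigid"]) : false;
    bs.far_ca = br.containsElementNamed("far_ca") ? as<int>(br["far_ca"]) - 1 : -1;
    IntegerVector z = br["zone"];
    for (int k = 0; k < z.size(); ++k) bs.zone.push_back(z[k] - 1);
    List axes = br["axes"];
    for (int a = 0; a < axes.size(); ++a) {
      List ax = axes[a];
      BreakSpec::Axis A;
      A.p = as<int>(ax["p"]) - 1;
      A.q = as<int>(ax["q"]) - 1;
      IntegerVector rot = ax["rot"];
      for (int k = 0; k < rot.size(); ++k) A.rot.push_back(rot[k] - 1);
      bs.axes.push_back(A);
    }
    out.push_back(bs);
  }
  return out;
}

// Close a break whose stationary flank runs unconstrained to a chain
// terminus: rotate the whole flank rigidly about its free-end CA (a hinge)
// so that the gap CA lands back at distance d0 from the moved region; if
// the hinge cannot reach (sphere-sphere miss), translate the flank instead.
static void close_terminal_flank(std::vector<double> &X, const BreakSpec &bs,
                                 double d0) {
  double P[3] = {X[3 * bs.far_ca], X[3 * bs.far_ca + 1], X[3 * bs.far_ca + 2]};
  double w[3] = {X[3 * bs.u] - P[0], X[3 * bs.u + 1] - P[1], X[3 * bs.u + 2] - P[2]};
  double rf = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  double dv[3] = {X[3 * bs.v] - P[0], X[3 * bs.v + 1] - P[1], X[3 * bs.v + 2] - P[2]};
  double dl = std::sqrt(dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2]);
  bool reachable = bs.far_ca != bs.u && rf > 1e-9 && dl > 1e-9 &&
                   dl <= rf + d0 && dl >= std::fabs(rf - d0);
  if (reachable) {
    // target point: intersection circle of spheres (P, rf) and (CA_v, d0),
    // taking the point nearest the current gap CA (smallest hinge turn)
    double n[3] = {dv[0] / dl, dv[1] / dl, dv[2] / dl};
    double a = (dl * dl + rf * rf - d0 * d0) / (2.0 * dl);
    double rc2 = rf * rf - a * a;
    double rc = rc2 > 0 ? std::sqrt(rc2) : 0.0;
    double C0[3] = {P[0] + a * n[0], P[1] + a * n[1], P[2] + a * n[2]};
    double e[3] = {X[3 * bs.u] - C0[0], X[3 * bs.u + 1] - C0[1], X[3 * bs.u + 2] - C0[2]};
    double edotn = e[0] * n[0] + e[1] * n[1] + e[2] * n[2];
    double ep[3] = {e[0] - edotn * n[0], e[1] - edotn * n[1], e[2] - edotn * n[2]};
    double epn = std::sqrt(ep[0] * ep[0] + ep[1] * ep[1] + ep[2] * ep[2]);
    if (epn < 1e-9) { // gap CA on the axis: pick any perpendicular
      ep[0] = n[1]; ep[1] = -n[0]; ep[2] = 0;
      epn = std::sqrt(ep[0] * ep[0] + ep[1] * ep[1] + ep[2] * ep[2]);
      if (epn < 1e-9) { ep[0] = 0; ep[1] = n[2]; ep[2] = -n[1];
        epn = std::sqrt(ep[0] * ep[0] + ep[1] * ep[1] + ep[2] * ep[2]); }
    }
    double Y[3] = {C0[0] + rc * ep[0] / epn, C0[1] + rc * ep[1] / epn,
                   C0[2] + rc * ep[2] / epn};
    double wp[3] = {Y[0] - P[0], Y[1] - P[1], Y[2] - P[2]};
    // rotate flank: axis w x w', angle between w and w'
    double ax[3] = {w[1] * wp[2] - w[2] * wp[1], w[2] * wp[0] - w[0] * wp[2],
                    w[0] * wp[1] - w[1] * wp[0]};
    double axn = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    double dot = w[0] * wp[0] + w[1] * wp[1] + w[2] * wp[2];
    if (axn > 1e-12) {
      double theta = std::atan2(axn, dot);
      double u3[3] = {ax[0] / axn, ax[1] / axn, ax[2] / axn};
      rotate_about(X, bs.zone, P, u3, theta);
      return;
    }
    if (dot > 0) return; // already aligned
  }
  // fallback: rigid translation along the gap vector
  double g[3] = {X[3 * bs.u] - X[3 * bs.v], X[3 * bs.u + 1] - X[3 * bs.v + 1],
                 X[3 * bs.u + 2] - X[3 * bs.v + 2]};
  double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
  if (gn > 1e-12) {
    double f = d0 / gn - 1.0;
    for (size_t k = 0; k < bs.zone.size(); ++k)
      for (int d = 0; d < 3; ++d)
        X[3 * bs.zone[k] + d] += f * g[d];
  }
}

// iterative closure of all breaks; returns residuals and convergence flag
static bool close_breaks(std::vector<double> &X,
                         const std::vector<BreakSpec> &breaks,
                         const std::vector<double> &d0, double tol,
                         int max_sweeps, double max_angle,
                         std::vector<double> &resid) {
  resid.assign(breaks.size(), 0.0);
  if (breaks.empty()) return true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool all_ok = true;
    for (size_t b = 0; b < breaks.size(); ++b) {
      const BreakSpec &bs = breaks[b];
      double res = std::fabs(dist3(X, bs.u, bs.v) - d0[b]);
      if (res <= tol) { resid[b] = res; continue; }
      all_ok = false;
      if (bs.rigid) {
        close_terminal_flank(X, bs, d0[b]);
      } else {
        for (size_t a = 0; a < bs.axes.size(); ++a)
          ccd_axis(X, bs.axes[a].p, bs.axes[a].q, bs.u, bs.v, d0[b],
                   bs.axes[a].rot, max_angle);
      }
      resid[b] = std::fabs(dist3(X, bs.u, bs.v) - d0[b]);
    }
    if (all_ok) break;
  }
  bool conv = true;
  for (size_t b = 0; b < breaks.size(); ++b) {
    resid[b] = std::fabs(dist3(X, breaks[b].u, breaks[b].v) - d0[b]);
    if (resid[b] > tol) conv = false;
  }
  return conv;
}

// [[Rcpp::export]]
List cpp_close_breaks(NumericMatrix coords, List breaks, NumericVector d0,
                      double tol, int max_sweeps, double max_angle) {
  int n = coords.nrow();
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);
  std::vector<BreakSpec> bs = parse_breaks(breaks);
  std::vector<double> dd(d0.begin(), d0.end());
  std::vector<double> resid;
  bool conv = close_breaks(X, bs, dd, tol, max_sweeps, max_angle, resid);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = X[3 * i + d];
  return List::create(_["coords"] = out, _["residuals"] = wrap(resid),
                      _["converged"] = conv);
}

struct NodeSpec {
  std::vector<int> idx;    // beads of the moved region
  std::vector<int> ca_idx; // CA beads (pivot centroid)
  std::vector<int> affected;
  double tmax, rmax, weight;
  std::vector<BreakSpec> breaks;
};

// [[Rcpp::export]]
List cpp_run_mcmc(NumericMatrix coords0, IntegerVector type, IntegerVector chain,
                  IntegerVector ord, IntegerVector group, NumericVector energies,
                  int nt, int nb, double bin_w, double cutoff, int min_sep,
                  double s0, double r0, List nodes, double A, double omega,
                  double shift, double t_ref, int n_steps, int snap_stride,
                  IntegerMatrix track_pairs, int track_stride, int resync_every,
                  double closure_tol, int closure_max_sweeps,
                  double closure_max_angle, bool store_snapshots) {
  FF ff = make_ff(energies, nt, nb, bin_w, cutoff, min_sep, s0, r0);
  int n = coords0.nrow();
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords0(i, d);

  // parse node specs
  int nn = nodes.size();
  std::vector<NodeSpec> ns(nn);
  std::vector<double> cumw(nn);
  double wsum = 0;
  for (int k = 0; k < nn; ++k) {
    List nd = nodes[k];
    IntegerVector idx = nd["idx"], ca = nd["ca_idx"], aff = nd["affected"];
    for (int i = 0; i < idx.size(); ++i) ns[k].idx.push_back(idx[i] - 1);
    for (int i = 0; i < ca.size(); ++i) ns[k].ca_idx.push_back(ca[i] - 1);
    for (int i = 0; i < aff.size(); ++i) ns[k].affected.push_back(aff[i] - 1);
    ns[k].tmax = as<double>(nd["tmax"]);
    ns[k].rmax = as<double>(nd["rmax"]);
    ns[k].weight = as<double>(nd["weight"]);
    ns[k].breaks = parse_breaks(nd["breaks"]);
    wsum += ns[k].weight;
    cumw[k] = wsum;
  }
  if (wsum <= 0) stop("run_mcmc: all node selection weights are zero");

  // masks per node for subset energy
  std::vector<std::vector<char> > masks(nn, std::vector<char>(n, 0));
  for (int k = 0; k < nn; ++k)
    for (size_t i = 0; i < ns[k].affected.size(); ++i)
      masks[k][ns[k].affected[i]] = 1;

  NumericVector e0 = cpp_total_energy(coords0, type, chain, ord, group, energies,
                                      nt, nb, bin_w, cutoff, min_sep, s0, r0);
  double E = e0[0];

  int n_snap = store_snapshots ? (n_steps / snap_stride + 1) : 0;
  NumericVector snaps(store_snapshots ? (size_t)n_snap * n * 3 : 0);
  IntegerVector snap_steps(store_snapshots ? n_snap : 0);
  int n_track_pairs = track_pairs.nrow();
  int n_track = (n_track_pairs > 0) ? (n_steps / track_stride + 1) : 0;
  NumericMatrix track(n_track, n_track_pairs);
  IntegerVector track_steps(n_track);

  NumericVector e_trace(n_steps), t_trace(n_steps);
  LogicalVector accepted(n_steps);
  IntegerVector node_trace(n_steps);
  IntegerVector acc_count(nn), prop_count(nn);
  int closure_fail = 0;
  int isnap = 0, itrack = 0;

  auto record = [&](int step) {
    if (store_snapshots && step % snap_stride == 0 && isnap < n_snap) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          snaps[(size_t)isnap + (size_t)n_snap * (i + (size_t)n * d)] = X[3 * i + d];
      snap_steps[isnap++] = step;
    }
    if (n_track_pairs > 0 && step % track_stride == 0 && itrack < n_track) {
      for (int p = 0; p < n_track_pairs; ++p)
        track(itrack, p) = dist3(X, track_pairs(p, 0) - 1, track_pairs(p, 1) - 1);
      track_steps[itrack] = step;
      ++itrack;
    }
  };
  record(0);

  std::vector<double> Xold_aff; // saved coordinates of affected beads
  std::vector<double> d0, resid;
  const double two_pi = 2.0 * M_PI;

  for (int k = 0; k < n_steps; ++k) {
    double T = shift + (A / 2.0) * (1.0 + std::cos(two_pi * (double)k / omega));
    // node selection
    double u = unif_rand() * wsum;
    int sel = 0;
    while (sel < nn - 1 && u > cumw[sel]) ++sel;
    prop_count[sel]++;
    NodeSpec &nd = ns[sel];
    NumericVector prop = cpp_propose(nd.tmax, nd.rmax);

    // pre-move gap lengths
    d0.resize(nd.breaks.size());
    for (size_t b = 0; b < nd.breaks.size(); ++b)
      d0[b] = dist3(X, nd.breaks[b].u, nd.breaks[b].v);

    // save affected coords
    Xold_aff.resize(3 * nd.affected.size());
    for (size_t i = 0; i < nd.affected.size(); ++i)
      for (int d = 0; d < 3; ++d)
        Xold_aff[3 * i + d] = X[3 * nd.affected[i] + d];

    double e_before = subset_energy(X, n, ff, type.begin(), chain.begin(),
                                    ord.begin(), masks[sel], nd.affected);

    // pivot = centroid of the node's CA beads
    double piv[3] = {0, 0, 0};
    for (size_t i = 0; i < nd.ca_idx.size(); ++i)
      for (int d = 0; d < 3; ++d) piv[d] += X[3 * nd.ca_idx[i] + d];
    for (int d = 0; d < 3; ++d) piv[d] /= (double)nd.ca_idx.size();

    double ax[3] = {prop[3], prop[4], prop[5]};
    rotate_about(X, nd.idx, piv, ax, prop[6] * M_PI / 180.0);
    for (size_t i = 0; i < nd.idx.size(); ++i)
      for (int d = 0; d < 3; ++d) X[3 * nd.idx[i] + d] += prop[d];

    bool ok = close_breaks(X, nd.breaks, d0, closure_tol, closure_max_sweeps,
                           closure_max_angle, resid);
    bool acc = false;
    if (!ok) {
      ++closure_fail;
    } else {
      double e_after = subset_energy(X, n, ff, type.begin(), chain.begin(),
                                     ord.begin(), masks[sel], nd.affected);
      double dE = e_after - e_before;
      if (dE <= 0) {
        acc = true;
      } else if (T > 0) {
        acc = unif_rand() < std::exp(-dE * t_ref / T);
      }
      if (acc) E += dE;
    }
    if (!acc) { // restore
      for (size_t i = 0; i < nd.affected.size(); ++i)
        for (int d = 0; d < 3; ++d)
          X[3 * nd.affected[i] + d] = Xold_aff[3 * i + d];
    } else {
      acc_count[sel]++;
    }
    e_trace[k] = E;
    t_trace[k] = T;
    accepted[k] = acc;
    node_trace[k] = sel + 1;

    if (resync_every > 0 && (k + 1) % resync_every == 0) {
      double full[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (excluded(ff, chain[i], chain[j], ord[i], ord[j])) continue;
          double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
                 dz = X[3 * i + 2] - X[3 * j + 2];
          full[0] += pair_e(ff, type[i] - 1, type[j] - 1, dx * dx + dy * dy + dz * dz);
        }
      if (std::fabs(full[0] - E) > std::max(1e-6, 1e-6 * std::fabs(full[0])))
        stop("run_mcmc: incremental energy desynchronised from full recompute (delta-energy bug)");
      E = full[0];
    }
    record(k + 1);
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) final_coords(i, d) = X[3 * i + d];
  List out = List::create(
      _["energy"] = e_trace, _["temperature"] = t_trace,
      _["accepted"] = accepted, _["node"] = node_trace,
      _["final_coords"] = final_coords, _["final_energy"] = E,
      _["acc_count"] = acc_count, _["prop_count"] = prop_count,
      _["closure_fail"] = closure_fail,
      _["track"] = track, _["track_steps"] = track_steps);
  if (store_snapshots) {
    snaps.attr("dim") = IntegerVector::create(n_snap, n, 3);
    out["snapshots"] = snaps;
    out["snap_steps"] = snap_steps;
  }
  return out;
}
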