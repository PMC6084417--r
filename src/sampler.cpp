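#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Bonded term kinds (must match the R-side encoding):
// 1 bond, 2 constraint, 3 angle (cosine-harmonic), 4 proper dihedral,
// 5 improper dihedral, 6 flat-bottom z restraint.
// Parameter columns arrive pre-converted: angle c0 = cos(theta0),
// dihedral phases / improper reference in radians.

static inline double dist3(const double *a, const double *b) {
  double dx = b[0] - a[0], dy = b[1] - a[1], dz = b[2] - a[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline void sub3(const double *a, const double *b, double *out) {
  out[0] = b[0] - a[0]; out[1] = b[1] - a[1]; out[2] = b[2] - a[2];
}

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static double cos_angle(const double *pi_, const double *pj, const double *pk) {
  double u[3], v[3];
  sub3(pj, pi_, u); sub3(pj, pk, v);
  double nu = std::sqrt(dot3(u, u)), nv = std::sqrt(dot3(v, v));
  if (nu < 1e-12 || nv < 1e-12) return 1.0;
  double c = dot3(u, v) / (nu * nv);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static double dihedral_rad(const double *p1, const double *p2,
                           const double *p3, const double *p4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  sub3(p1, p2, b1); sub3(p2, p3, b2); sub3(p3, p4, b3);
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double nb2 = std::sqrt(dot3(b2, b2));
  if (nb2 < 1e-12) return 0.0;
  cross3(n1, n2, m);
  double y = dot3(m, b2) / nb2;
  double x = dot3(n1, n2);
  return std::atan2(y, x);
}

static double term_energy(int kind, const int *idx, const double *par,
                          const double *pos, int n) {
  const double *p1 = pos + 3 * (idx[0] - 1);
  switch (kind) {
  case 1: { // harmonic bond
    const double *p2 = pos + 3 * (idx[1] - 1);
    double d = dist3(p1, p2) - par[0];
    return 0.5 * par[1] * d * d;
  }
  case 2: // constraint: rigid, no energy
    return 0.0;
  case 3: { // cosine-harmonic angle on cos(theta)
    const double *p2 = pos + 3 * (idx[1] - 1);
    const double *p3 = pos + 3 * (idx[2] - 1);
    double d = cos_angle(p1, p2, p3) - par[0];
    return 0.5 * par[1] * d * d;
  }
  case 4: { // periodic proper dihedral
    const double *p2 = pos + 3 * (idx[1] - 1);
    const double *p3 = pos + 3 * (idx[2] - 1);
    const double *p4 = pos + 3 * (idx[3] - 1);
    double phi = dihedral_rad(p1, p2, p3, p4);
    return par[1] * (1.0 + std::cos(par[2] * phi - par[0]));
  }
  case 5: { // harmonic improper dihedral
    const double *p2 = pos + 3 * (idx[1] - 1);
    const double *p3 = pos + 3 * (idx[2] - 1);
    const double *p4 = pos + 3 * (idx[3] - 1);
    double dxi = dihedral_rad(p1, p2, p3, p4) - par[0];
    while (dxi > M_PI) dxi -= 2.0 * M_PI;
    while (dxi < -M_PI) dxi += 2.0 * M_PI;
    return 0.5 * par[1] * dxi * dxi;
  }
  case 6: { // flat-bottom restraint on |z - zref|
    double dz = std::fabs(p1[2] - par[2]);
    if (dz <= par[0]) return 0.0;
    double d = dz - par[0];
    return 0.5 * par[1] * d * d;
  }
  default:
    Rcpp::stop("unknown term kind");
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_term_energies(NumericVector pos, IntegerMatrix tidx,
                                IntegerVector tkind, NumericMatrix tpar) {
  int nt = tkind.size();
  int n = pos.size() / 3;
  NumericVector out(nt);
  std::vector<double> p(pos.begin(), pos.end());
  for (int t = 0; t < nt; ++t) {
    int idx[4] = {tidx(t, 0), tidx(t, 1), tidx(t, 2), tidx(t, 3)};
    double par[3] = {tpar(t, 0), tpar(t, 1), tpar(t, 2)};
    out[t] = term_energy(tkind[t], idx, par, p.data(), n);
  }
  return out;
}

// Metropolis Monte Carlo over the bonded energy. Positions are row-major
// (x1,y1,z1,x2,...). `groups` lists rigid move groups (1-based bead index
// vectors); singleton groups get displacement moves, larger groups rigid
// translation+rotation so internal constraints stay exact.
// [[Rcpp::export]]
List cpp_sample(NumericVector pos0, IntegerMatrix tidx, IntegerVector tkind,
                NumericMatrix tpar, List groups, List pivots, double p_pivot,
                double kT, int n_steps, double trans_step, double rot_step,
                int sample_every, int seed) {
  int n = pos0.size() / 3;
  int nt = tkind.size();
  std::vector<double> pos(pos0.begin(), pos0.end());
  int ng = groups.size();
  std::vector<std::vector<int>> grp(ng);
  for (int g = 0; g < ng; ++g) {
    IntegerVector v = groups[g];
    for (int k = 0; k < v.size(); ++k) grp[g].push_back(v[k] - 1);
  }
  // incidence: terms touching each group
  std::vector<std::vector<int>> inc(ng);
  std::vector<int> bead2grp(n, -1);
  for (int g = 0; g < ng; ++g)
    for (int b : grp[g]) bead2grp[b] = g;
  for (int t = 0; t < nt; ++t) {
    int na = (tkind[t] == 6) ? 1 : (tkind[t] <= 2 ? 2 : (tkind[t] == 3 ? 3 : 4));
    std::vector<int> seen;
    for (int a = 0; a < na; ++a) {
      int g = bead2grp[tidx(t, a) - 1];
      if (g >= 0 &&
          std::find(seen.begin(), seen.end(), g) == seen.end()) {
        inc[g].push_back(t);
        seen.push_back(g);
      }
    }
  }
  // pivot moves: each entry = (axis_i, axis_j, moved beads...); rotating
  // the moved set about the axis decorrelates torsions and angles fast
  int np = pivots.size();
  std::vector<int> piv_a(np), piv_b(np);
  std::vector<std::vector<int>> piv_moved(np), piv_inc(np);
  for (int pv = 0; pv < np; ++pv) {
    IntegerVector v = pivots[pv];
    piv_a[pv] = v[0] - 1; piv_b[pv] = v[1] - 1;
    std::vector<bool> inmoved(n, false);
    for (int k = 2; k < v.size(); ++k) {
      piv_moved[pv].push_back(v[k] - 1);
      inmoved[v[k] - 1] = true;
    }
    for (int t = 0; t < nt; ++t) {
      int na = (tkind[t] == 6) ? 1 : (tkind[t] <= 2 ? 2 : (tkind[t] == 3 ? 3 : 4));
      bool any_in = false, any_out = false;
      for (int a = 0; a < na; ++a) {
        if (inmoved[tidx(t, a) - 1]) any_in = true; else any_out = true;
      }
      if (any_in && any_out) piv_inc[pv].push_back(t);
    }
  }
  if (np == 0) p_pivot = 0.0;
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  int n_samples = n_steps / sample_every;
  NumericVector samples(static_cast<R_xlen_t>(n_samples) * n * 3);
  long accepted = 0;
  std::vector<double> trial(3 * 12);

  for (int step = 1; step <= n_steps; ++step) {
    bool do_pivot = unif(rng) < p_pivot;
    int g = -1, pv = -1;
    if (do_pivot) {
      pv = static_cast<int>(unif(rng) * np);
      if (pv >= np) pv = np - 1;
    } else {
      g = static_cast<int>(unif(rng) * ng);
      if (g >= ng) g = ng - 1;
    }
    const std::vector<int> &beads = do_pivot ? piv_moved[pv] : grp[g];
    const std::vector<int> &incid = do_pivot ? piv_inc[pv] : inc[g];
    int m = beads.size();
    if (static_cast<int>(trial.size()) < 3 * m) trial.resize(3 * m);
    // old energy of incident terms
    double e_old = 0.0;
    for (int t : incid) {
      int idx[4] = {tidx(t, 0), tidx(t, 1), tidx(t, 2), tidx(t, 3)};
      double par[3] = {tpar(t, 0), tpar(t, 1), tpar(t, 2)};
      e_old += term_energy(tkind[t], idx, par, pos.data(), n);
    }
    // propose
    double dx = (2.0 * unif(rng) - 1.0) * trans_step;
    double dy = (2.0 * unif(rng) - 1.0) * trans_step;
    double dz = (2.0 * unif(rng) - 1.0) * trans_step;
    std::vector<double> saved(3 * m);
    for (int k = 0; k < m; ++k)
      for (int c = 0; c < 3; ++c) saved[3 * k + c] = pos[3 * beads[k] + c];
    if (do_pivot) {
      double ox = pos[3 * piv_a[pv]], oy = pos[3 * piv_a[pv] + 1],
             oz = pos[3 * piv_a[pv] + 2];
      double ax = pos[3 * piv_b[pv]] - ox, ay = pos[3 * piv_b[pv] + 1] - oy,
             az = pos[3 * piv_b[pv] + 2] - oz;
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
      ax /= an; ay /= an; az /= an;
      double th = (2.0 * unif(rng) - 1.0) * M_PI;
      double ct = std::cos(th), st = std::sin(th);
      for (int k = 0; k < m; ++k) {
        double vx = saved[3 * k] - ox, vy = saved[3 * k + 1] - oy,
               vz = saved[3 * k + 2] - oz;
        double axv_x = ay * vz - az * vy;
        double axv_y = az * vx - ax * vz;
        double axv_z = ax * vy - ay * vx;
        double ad = ax * vx + ay * vy + az * vz;
        pos[3 * beads[k] + 0] = ox + vx * ct + axv_x * st + ax * ad * (1 - ct);
        pos[3 * beads[k] + 1] = oy + vy * ct + axv_y * st + ay * ad * (1 - ct);
        pos[3 * beads[k] + 2] = oz + vz * ct + axv_z * st + az * ad * (1 - ct);
      }
    } else if (m == 1) {
      pos[3 * beads[0] + 0] += dx;
      pos[3 * beads[0] + 1] += dy;
      pos[3 * beads[0] + 2] += dz;
    } else {
      // rigid move: rotate about random axis through centroid, then shift
      double cx = 0, cy = 0, cz = 0;
      for (int k = 0; k < m; ++k) {
        cx += saved[3 * k]; cy += saved[3 * k + 1]; cz += saved[3 * k + 2];
      }
      cx /= m; cy /= m; cz /= m;
      double ax = gauss(rng), ay = gauss(rng), az = gauss(rng);
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
      ax /= an; ay /= an; az /= an;
      double th = (2.0 * unif(rng) - 1.0) * rot_step;
      double ct = std::cos(th), st = std::sin(th);
      for (int k = 0; k < m; ++k) {
        double vx = saved[3 * k] - cx, vy = saved[3 * k + 1] - cy,
               vz = saved[3 * k + 2] - cz;
        double axv_x = ay * vz - az * vy;
        double axv_y = az * vx - ax * vz;
        double axv_z = ax * vy - ay * vx;
        double ad = ax * vx + ay * vy + az * vz;
        double rx = vx * ct + axv_x * st + ax * ad * (1 - ct);
        double ry = vy * ct + axv_y * st + ay * ad * (1 - ct);
        double rz = vz * ct + axv_z * st + az * ad * (1 - ct);
        pos[3 * beads[k] + 0] = cx + rx + dx;
        pos[3 * beads[k] + 1] = cy + ry + dy;
        pos[3 * beads[k] + 2] = cz + rz + dz;
      }
    }
    double e_new = 0.0;
    for (int t : incid) {
      int idx[4] = {tidx(t, 0), tidx(t, 1), tidx(t, 2), tidx(t, 3)};
      double par[3] = {tpar(t, 0), tpar(t, 1), tpar(t, 2)};
      e_new += term_energy(tkind[t], idx, par, pos.data(), n);
    }
    double dE = e_new - e_old;
    bool accept = dE <= 0.0 || unif(rng) < std::exp(-dE / kT);
    if (accept) {
      ++accepted;
    } else {
      for (int k = 0; k < m; ++k)
        for (int c = 0; c < 3; ++c) pos[3 * beads[k] + c] = saved[3 * k + c];
    }
    if (step % sample_every == 0) {
      R_xlen_t off = static_cast<R_xlen_t>(step / sample_every - 1) * n * 3;
      for (int k = 0; k < 3 * n; ++k) samples[off + k] = pos[k];
    }
  }
  return List::create(
    _["samples"] = samples,
    _["n_samples"] = n_samples,
    _["acceptance"] = static_cast<double>(accepted) / n_steps,
    _["final"] = NumericVector(pos.begin(), pos.end()));
}
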