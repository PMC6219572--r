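// Rigid-body Metropolis Monte Carlo with simulated annealing for N-BAR
// proteins in a periodic 2D box.  Proteins are rigid unions of capsules
// (segment + radius) for sterics; inter-protein energies are the tabulated
// H0-H0 wedge pair potential (looked up by relative pose of the H0 frames)
// plus, optionally, a modified Lennard-Jones BAR-BAR pair potential.
// Energies are in units of k_B * T_rm; the temperature is dimensionless in
// units of T_rm.  All randomness comes from R's RNG, so runs are fully
// reproducible from set.seed().
//
// Rotated body geometry is cached per protein (relative to the protein
// center), so translation trials need no trigonometry and pair evaluations
// reuse the cache; all distance prescreens compare squared distances.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Shape {
  // body-frame capsules
  std::vector<double> bx1, by1, bx2, by2, cr;
  std::vector<double> hl;          // capsule half lengths (rotation invariant)
  double h0cx[2], h0cy[2], h0phi[2];
  double reach;                    // max distance from center to capsule surface
  int m;
};

struct Table {
  std::vector<double> gx, gy, gth; // gth uniform on [0, pi)
  std::vector<double> E;           // [i + nx*(j + ny*k)]
  int nx, ny, nth;
  double xmax, ymax, range2;       // range2 = xmax^2 + ymax^2
  double r0, half_core;            // H0 stadium hardcore geometry
};

struct BarPot { bool on; double eps, rm; };

// rotated (not translated) geometry of one protein
struct RotGeom {
  std::vector<double> x1, y1, x2, y2;   // capsule endpoints, m each
  double hx[2], hy[2], hphi[2];         // H0 centers and world axis angles
};

struct Sys {
  int n;
  double box;
  Shape shape;
  Table tab;
  BarPot bar;
  double caps_cut2, h0_cut2;       // squared center-distance cutoffs
  std::vector<double> x, y, th;
  std::vector<RotGeom> rot;        // cached rotated geometry per protein
};

// positive modulo without std::fmod (portable across glibc symbol versions)
inline double pmod(double v, double m) {
  double r = v - m * std::floor(v / m);
  if (r >= m) r -= m;
  if (r < 0) r = 0;
  return r;
}
inline double wrap(double v, double box) { return pmod(v, box); }
inline double mind(double v, double box) {
  if (v > 0.5 * box) v -= box;
  else if (v < -0.5 * box) v += box;
  return v;
}

// squared minimum distance between segments p1-p2 and q1-q2
double seg_dist2(double p1x, double p1y, double p2x, double p2y,
                 double q1x, double q1y, double q2x, double q2y) {
  const double d1x = p2x - p1x, d1y = p2y - p1y;
  const double d2x = q2x - q1x, d2y = q2y - q1y;
  const double rx = p1x - q1x, ry = p1y - q1y;
  const double a = d1x * d1x + d1y * d1y;
  const double e = d2x * d2x + d2y * d2y;
  const double f = d2x * rx + d2y * ry;
  double s = 0.0, t = 0.0;
  if (a <= 1e-14 && e <= 1e-14) {
    // both degenerate
  } else if (a <= 1e-14) {
    t = std::min(std::max(f / e, 0.0), 1.0);
  } else {
    const double c = d1x * rx + d1y * ry;
    if (e <= 1e-14) {
      s = std::min(std::max(-c / a, 0.0), 1.0);
    } else {
      const double b = d1x * d2x + d1y * d2y;
      const double den = a * e - b * b;
      if (den > 1e-14) s = std::min(std::max((b * f - c * e) / den, 0.0), 1.0);
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(std::max(-c / a, 0.0), 1.0); }
      else if (t > 1) { t = 1; s = std::min(std::max((b - c) / a, 0.0), 1.0); }
    }
  }
  const double cx = p1x + s * d1x - (q1x + t * d2x);
  const double cy = p1y + s * d1y - (q1y + t * d2y);
  return cx * cx + cy * cy;
}

// trilinear lookup with stadium mirror symmetries; mirrors the R-side
// pair_potential() exactly
double table_lookup(const Table& tab, double dx, double dy, double dth) {
  if (dx * dx + dy * dy > tab.range2) return 0.0;  // cannot be in range
  // hardcore from exact capsule geometry of the two H0 stadiums
  const double hc = tab.half_core;
  const double c2 = std::cos(dth), s2 = std::sin(dth);
  const double d2 = seg_dist2(-hc, 0.0, hc, 0.0,
                              dx - hc * c2, dy - hc * s2,
                              dx + hc * c2, dy + hc * s2);
  if (d2 < 4.0 * tab.r0 * tab.r0) return INF;
  if (dx < 0) { dx = -dx; dth = -dth; }
  if (dy < 0) { dy = -dy; dth = -dth; }
  dth = pmod(dth, M_PI);
  if (dx > tab.xmax || dy > tab.ymax) return 0.0;
  int i = int(std::upper_bound(tab.gx.begin(), tab.gx.end(), dx) - tab.gx.begin()) - 1;
  i = std::min(std::max(i, 0), tab.nx - 2);
  int j = int(std::upper_bound(tab.gy.begin(), tab.gy.end(), dy) - tab.gy.begin()) - 1;
  j = std::min(std::max(j, 0), tab.ny - 2);
  double wx = (dx - tab.gx[i]) / (tab.gx[i + 1] - tab.gx[i]);
  double wy = (dy - tab.gy[j]) / (tab.gy[j + 1] - tab.gy[j]);
  wx = std::min(std::max(wx, 0.0), 1.0);
  wy = std::min(std::max(wy, 0.0), 1.0);
  const double step = M_PI / tab.nth;
  const double u = dth / step;
  int k0 = int(std::floor(u)) % tab.nth;
  const double wt = u - std::floor(u);
  int k1 = (k0 + 1) % tab.nth;
  auto val_th = [&](int k) {
    double e[4] = { tab.E[i + tab.nx * (j + tab.ny * k)],
                    tab.E[i + 1 + tab.nx * (j + tab.ny * k)],
                    tab.E[i + tab.nx * (j + 1 + tab.ny * k)],
                    tab.E[i + 1 + tab.nx * (j + 1 + tab.ny * k)] };
    double mx = 0.0;
    bool anyinf = false;
    for (int q = 0; q < 4; ++q) {
      if (std::isinf(e[q])) anyinf = true;
      else mx = std::max(mx, e[q]);
    }
    if (anyinf)
      for (int q = 0; q < 4; ++q) if (std::isinf(e[q])) e[q] = mx;
    return (1 - wx) * ((1 - wy) * e[0] + wy * e[2]) +
           wx * ((1 - wy) * e[1] + wy * e[3]);
  };
  return (1 - wt) * val_th(k0) + wt * val_th(k1);
}

double bar_energy(double r, double t1, double t2, const BarPot& bar) {
  const double q6 = std::pow(bar.rm / r, 6);
  const double ang = 1.0 - std::fabs(2.0 * t1 - M_PI) / (2.0 * M_PI)
                         - std::fabs(2.0 * t2 - M_PI) / (2.0 * M_PI);
  return bar.eps * (q6 * q6 - 2.0 * q6 * ang);
}

void fill_rot(const Shape& sh, double ti, RotGeom& g) {
  const double c = std::cos(ti), s = std::sin(ti);
  for (int q = 0; q < sh.m; ++q) {
    g.x1[q] = c * sh.bx1[q] - s * sh.by1[q];
    g.y1[q] = s * sh.bx1[q] + c * sh.by1[q];
    g.x2[q] = c * sh.bx2[q] - s * sh.by2[q];
    g.y2[q] = s * sh.bx2[q] + c * sh.by2[q];
  }
  for (int a = 0; a < 2; ++a) {
    g.hx[a] = c * sh.h0cx[a] - s * sh.h0cy[a];
    g.hy[a] = s * sh.h0cx[a] + c * sh.h0cy[a];
    g.hphi[a] = ti + sh.h0phi[a];
  }
}

// interaction energy of protein i (candidate pose xi, yi, geometry gi) with
// protein j at its cached pose
double pair_energy_g(const Sys& S, const RotGeom& gi, double xi, double yi,
                     double ti, int j) {
  const double dx = mind(S.x[j] - xi, S.box);
  const double dy = mind(S.y[j] - yi, S.box);
  const double rc2 = dx * dx + dy * dy;
  double E = 0.0;
  if (S.bar.on && rc2 > 1e-18) {
    const double phi = std::atan2(dy, dx);
    const double t1 = pmod(ti - phi, M_PI);
    const double t2 = pmod(S.th[j] - phi, M_PI);
    E += bar_energy(std::sqrt(rc2), t1, t2, S.bar);
  }
  const RotGeom& gj = S.rot[j];
  if (rc2 < S.caps_cut2) {
    const int m = S.shape.m;
    for (int qa = 0; qa < m; ++qa) {
      const double ax = 0.5 * (gi.x1[qa] + gi.x2[qa]);
      const double ay = 0.5 * (gi.y1[qa] + gi.y2[qa]);
      for (int qb = 0; qb < m; ++qb) {
        const double rr = S.shape.cr[qa] + S.shape.cr[qb];
        const double lim = S.shape.hl[qa] + S.shape.hl[qb] + rr;
        const double mx = dx + 0.5 * (gj.x1[qb] + gj.x2[qb]) - ax;
        const double my = dy + 0.5 * (gj.y1[qb] + gj.y2[qb]) - ay;
        if (mx * mx + my * my > lim * lim) continue;
        if (seg_dist2(gi.x1[qa], gi.y1[qa], gi.x2[qa], gi.y2[qa],
                      dx + gj.x1[qb], dy + gj.y1[qb],
                      dx + gj.x2[qb], dy + gj.y2[qb]) < rr * rr) return INF;
      }
    }
  }
  if (rc2 > S.h0_cut2) return E;
  // four inter-protein H0-H0 terms; the lookup is averaged over the two
  // frame conventions so the pair energy is exactly symmetric under i <-> j
  // (interpolation on the non-uniform grid would otherwise break it)
  for (int a = 0; a < 2; ++a) {
    const double pha = gi.hphi[a];
    const double ca = std::cos(pha), sa = std::sin(pha);
    for (int b = 0; b < 2; ++b) {
      const double rx = dx + gj.hx[b] - gi.hx[a];
      const double ry = dy + gj.hy[b] - gi.hy[a];
      if (rx * rx + ry * ry > S.tab.range2) continue;
      const double phb = gj.hphi[b];
      const double e1 = table_lookup(S.tab, ca * rx + sa * ry,
                                     -sa * rx + ca * ry, phb - pha);
      if (std::isinf(e1)) return INF;
      const double cb = std::cos(phb), sb = std::sin(phb);
      const double e2 = table_lookup(S.tab, -(cb * rx + sb * ry),
                                     sb * rx - cb * ry, pha - phb);
      if (std::isinf(e2)) return INF;
      E += 0.5 * (e1 + e2);
    }
  }
  return E;
}

double energy_of_g(const Sys& S, int i, const RotGeom& gi,
                   double xi, double yi, double ti) {
  double E = 0.0;
  for (int j = 0; j < S.n; ++j) {
    if (j == i) continue;
    const double e = pair_energy_g(S, gi, xi, yi, ti, j);
    if (std::isinf(e)) return INF;
    E += e;
  }
  return E;
}

double total_energy_sys(const Sys& S) {
  double E = 0.0;
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      const double e = pair_energy_g(S, S.rot[i], S.x[i], S.y[i], S.th[i], j);
      if (std::isinf(e)) return INF;
      E += e;
    }
  return E;
}

Sys build_sys(NumericMatrix poses, double box, List shape, List table, List bar) {
  Sys S;
  S.n = poses.nrow();
  S.box = box;
  S.x.resize(S.n); S.y.resize(S.n); S.th.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = wrap(poses(i, 0), box);
    S.y[i] = wrap(poses(i, 1), box);
    S.th[i] = poses(i, 2);
  }
  NumericMatrix caps = shape["capsules"];
  S.shape.m = caps.nrow();
  S.shape.reach = 0.0;
  for (int q = 0; q < S.shape.m; ++q) {
    S.shape.bx1.push_back(caps(q, 0)); S.shape.by1.push_back(caps(q, 1));
    S.shape.bx2.push_back(caps(q, 2)); S.shape.by2.push_back(caps(q, 3));
    S.shape.cr.push_back(caps(q, 4));
    S.shape.hl.push_back(0.5 * std::hypot(caps(q, 2) - caps(q, 0),
                                          caps(q, 3) - caps(q, 1)));
    S.shape.reach = std::max(S.shape.reach,
      std::max(std::hypot(caps(q, 0), caps(q, 1)),
               std::hypot(caps(q, 2), caps(q, 3))) + caps(q, 4));
  }
  NumericMatrix h0 = shape["h0_frames"];
  for (int a = 0; a < 2; ++a) {
    S.shape.h0cx[a] = h0(a, 0); S.shape.h0cy[a] = h0(a, 1);
    S.shape.h0phi[a] = h0(a, 2);
  }
  S.tab.gx = as<std::vector<double> >(table["dx"]);
  S.tab.gy = as<std::vector<double> >(table["dy"]);
  S.tab.gth = as<std::vector<double> >(table["dtheta"]);
  NumericVector E = table["E"];
  S.tab.E = as<std::vector<double> >(E);
  S.tab.nx = S.tab.gx.size(); S.tab.ny = S.tab.gy.size();
  S.tab.nth = S.tab.gth.size();
  S.tab.xmax = S.tab.gx.back(); S.tab.ymax = S.tab.gy.back();
  S.tab.range2 = S.tab.xmax * S.tab.xmax + S.tab.ymax * S.tab.ymax;
  List wedge = table["wedge"];
  S.tab.r0 = as<double>(wedge["r0"]);
  S.tab.half_core = as<double>(wedge["L"]) / 2.0 - S.tab.r0;
  S.bar.on = as<bool>(bar["on"]);
  S.bar.eps = as<double>(bar["eps"]);
  S.bar.rm = as<double>(bar["rm"]);
  double h0max = 0.0;
  for (int a = 0; a < 2; ++a)
    h0max = std::max(h0max, std::hypot(S.shape.h0cx[a], S.shape.h0cy[a]));
  const double ccut = 2.0 * S.shape.reach;
  const double hcut = 2.0 * h0max + std::sqrt(S.tab.range2) +
    2.0 * S.tab.half_core;
  S.caps_cut2 = ccut * ccut;
  S.h0_cut2 = hcut * hcut;
  RotGeom proto;
  proto.x1.resize(S.shape.m); proto.y1.resize(S.shape.m);
  proto.x2.resize(S.shape.m); proto.y2.resize(S.shape.m);
  S.rot.assign(S.n, proto);
  for (int i = 0; i < S.n; ++i) fill_rot(S.shape, S.th[i], S.rot[i]);
  return S;
}

// core MC loop: n_steps at temperature schedule T(step)
template <typename TempFn>
List run_mc(Sys& S, long n_steps, TempFn temp, double dr, double dth,
            long record_every) {
  RNGScope scope;
  double Etot = total_energy_sys(S);
  std::vector<double> tr_step, tr_T, tr_E;
  std::vector<int> order(S.n);
  for (int i = 0; i < S.n; ++i) order[i] = i;
  RotGeom scratch = S.rot[0];
  for (long step = 0; step < n_steps; ++step) {
    const double T = temp(step);
    // fresh shuffled order per step
    for (int i = S.n - 1; i > 0; --i) {
      int j = int(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int q = 0; q < S.n; ++q) {
      const int i = order[q];
      // translation then rotation trial
      for (int kind = 0; kind < 2; ++kind) {
        double xi = S.x[i], yi = S.y[i], ti = S.th[i];
        const RotGeom* gi = &S.rot[i];
        if (kind == 0) {
          xi = wrap(xi + dr * (2.0 * unif_rand() - 1.0), S.box);
          yi = wrap(yi + dr * (2.0 * unif_rand() - 1.0), S.box);
        } else {
          ti = ti + dth * (2.0 * unif_rand() - 1.0);
          if (ti > M_PI) ti -= 2.0 * M_PI;
          if (ti < -M_PI) ti += 2.0 * M_PI;
          fill_rot(S.shape, ti, scratch);
          gi = &scratch;
        }
        const double Enew = energy_of_g(S, i, *gi, xi, yi, ti);
        if (std::isinf(Enew)) continue;           // overlap: always rejected
        const double Eold = energy_of_g(S, i, S.rot[i], S.x[i], S.y[i], S.th[i]);
        const double dE = Enew - Eold;
        bool accept;
        if (dE <= 0) accept = true;
        else if (T > 0) accept = (unif_rand() < std::exp(-dE / T));
        else accept = false;
        if (accept) {
          S.x[i] = xi; S.y[i] = yi;
          if (kind == 1) { S.th[i] = ti; std::swap(S.rot[i], scratch); }
          Etot += dE;
        }
      }
    }
    if (record_every > 0 && (step % record_every == 0 || step == n_steps - 1)) {
      tr_step.push_back(double(step));
      tr_T.push_back(T);
      tr_E.push_back(Etot);
    }
  }
  // exact final energy (guards against accumulation roundoff)
  Etot = total_energy_sys(S);
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    out(i, 0) = S.x[i]; out(i, 1) = S.y[i]; out(i, 2) = S.th[i];
  }
  return List::create(_["poses"] = out, _["energy"] = Etot,
                      _["trace"] = DataFrame::create(
                        _["step"] = tr_step, _["T"] = tr_T, _["energy"] = tr_E));
}

} // namespace

// [[Rcpp::export]]
double mc_total_energy(NumericMatrix poses, double box, List shape,
                       List table, List bar) {
  Sys S = build_sys(poses, box, shape, table, bar);
  return total_energy_sys(S);
}

// [[Rcpp::export]]
bool mc_any_overlap(NumericMatrix poses, double box, List shape,
                    List table, List bar) {
  Sys S = build_sys(poses, box, shape, table, bar);
  return std::isinf(total_energy_sys(S));
}

// [[Rcpp::export]]
NumericVector mc_pair_lookup(List table, NumericVector dx, NumericVector dy,
                             NumericVector dth) {
  Table tab;
  tab.gx = as<std::vector<double> >(table["dx"]);
  tab.gy = as<std::vector<double> >(table["dy"]);
  tab.gth = as<std::vector<double> >(table["dtheta"]);
  tab.E = as<std::vector<double> >(as<NumericVector>(table["E"]));
  tab.nx = tab.gx.size(); tab.ny = tab.gy.size(); tab.nth = tab.gth.size();
  tab.xmax = tab.gx.back(); tab.ymax = tab.gy.back();
  tab.range2 = tab.xmax * tab.xmax + tab.ymax * tab.ymax;
  List wedge = table["wedge"];
  tab.r0 = as<double>(wedge["r0"]);
  tab.half_core = as<double>(wedge["L"]) / 2.0 - tab.r0;
  const int n = dx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = table_lookup(tab, dx[i], dy[i], dth[i]);
  return out;
}

// [[Rcpp::export]]
List mc_run(NumericMatrix poses, double box, List shape, List table, List bar,
            double n_hot, double n_cool, double T_hot, double dr, double dth,
            double record_every) {
  Sys S = build_sys(poses, box, shape, table, bar);
  const long nh = long(n_hot), nc = long(n_cool);
  const long rec = long(record_every);
  auto temp = [&](long step) {
    if (step < nh) return T_hot;
    if (nc <= 0) return 0.0;
    const double f = 1.0 - double(step - nh + 1) / double(nc);
    return T_hot * std::max(f, 0.0);
  };
  return run_mc(S, nh + nc, temp, dr, dth, rec);
}

// [[Rcpp::export]]
List mc_sweep(NumericMatrix poses, double box, List shape, List table, List bar,
              double T, double n_steps, double dr, double dth,
              double record_every) {
  Sys S = build_sys(poses, box, shape, table, bar);
  auto temp = [&](long) { return T; };
  return run_mc(S, long(n_steps), temp, dr, dth, long(record_every));
}
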