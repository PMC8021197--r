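// Core kernels: force field evaluation, Gear 5th-order predictor-corrector
// Langevin integration, dynamic contact registry and wall bookkeeping.
// Positions are in nm, energies in epsilon, time in tau.  The box is
// periodic in X/Y; flat walls sit at Z = 0 (fixed) and Z = s (moving).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <random>

using namespace Rcpp;

static const double SIX = 1.1224620483093730; // 2^(1/6)

// ---------------------------------------------------------------------------
// parameter bundle ----------------------------------------------------------

struct Par {
  double dt, mass, gamma, temperature;
  double k_bond, r_b, r_o, sigma0;
  double f_cut, t_switch, bb_multiplier, ss_depth, SS_depth;
  double r_min_SS, bb_min, bs_min;
  NumericMatrix ss_min; // 20 x 20 LJ-minimum distances for ss pairs (nm)
  double align_thr;
  double coulomb, perm_slope, debye, elec_cutoff;
  bool any_charges;
  double cap_r, skin, max_disp;
  double wall_depth, wall_dmin, wall_detach;
  std::vector<double> ka, th0, kd1, p1, kd3, p3;
  double nb_cutoff; // pair interaction range for the Verlet list
};

static std::vector<double> numvec(List l, const char* nm) {
  NumericVector v = l[nm];
  return std::vector<double>(v.begin(), v.end());
}

static Par read_par(List p) {
  Par q;
  q.dt = p["dt"]; q.mass = p["mass"]; q.gamma = p["gamma"];
  q.temperature = p["temperature"];
  q.k_bond = p["k_bond"]; q.r_b = p["r_b"]; q.r_o = p["r_o"];
  q.sigma0 = p["sigma0"];
  q.f_cut = p["f_cut"]; q.t_switch = p["t_switch"];
  q.bb_multiplier = p["bb_multiplier"]; q.ss_depth = p["ss_depth"];
  q.SS_depth = p["SS_depth"]; q.r_min_SS = p["r_min_SS"];
  q.bb_min = p["bb_min"]; q.bs_min = p["bs_min"];
  q.ss_min = as<NumericMatrix>(p["ss_min"]);
  q.align_thr = p["align_thr"];
  q.coulomb = p["coulomb"]; q.perm_slope = p["perm_slope"];
  q.debye = p["debye"]; q.elec_cutoff = p["elec_cutoff"];
  q.any_charges = p["any_charges"];
  q.cap_r = p["cap_r"]; q.skin = p["skin"]; q.max_disp = p["max_disp"];
  q.wall_depth = p["wall_depth"]; q.wall_dmin = p["wall_dmin"];
  q.wall_detach = p["wall_detach"];
  q.ka = numvec(p, "ka"); q.th0 = numvec(p, "th0");
  q.kd1 = numvec(p, "kd1"); q.p1 = numvec(p, "p1");
  q.kd3 = numvec(p, "kd3"); q.p3 = numvec(p, "p3");
  // range needed to see every candidate pair and every cut-off interaction
  double mx = q.r_o;
  if (q.bb_min > mx) mx = q.bb_min;
  if (q.bs_min > mx) mx = q.bs_min;
  if (q.r_min_SS > mx) mx = q.r_min_SS;
  for (int a = 0; a < q.ss_min.nrow(); ++a)
    for (int b = 0; b < q.ss_min.ncol(); ++b)
      if (q.ss_min(a, b) > mx) mx = q.ss_min(a, b);
  if (q.any_charges && q.elec_cutoff > mx) mx = q.elec_cutoff;
  q.nb_cutoff = mx;
  return q;
}

// ---------------------------------------------------------------------------
// topology bundle -----------------------------------------------------------

struct Topo {
  int n;
  std::vector<int> chain, type, cls, is_cys;
  std::vector<double> charge, bb_cap, ss_cap;
};

static Topo read_topo(List t) {
  Topo o;
  IntegerVector ch = t["chain_of"], ty = t["type_idx"], cl = t["class_idx"],
                cy = t["is_cys"];
  NumericVector q = t["charge"], bc = t["bb_cap"], sc = t["ss_cap"];
  o.n = ch.size();
  o.chain.assign(ch.begin(), ch.end());
  o.type.assign(ty.begin(), ty.end());
  o.cls.assign(cl.begin(), cl.end());
  o.is_cys.assign(cy.begin(), cy.end());
  o.charge.assign(q.begin(), q.end());
  o.bb_cap.assign(bc.begin(), bc.end());
  o.ss_cap.assign(sc.begin(), sc.end());
  return o;
}

// ---------------------------------------------------------------------------
// mutable system ------------------------------------------------------------

// registry kinds
enum { K_BB = 0, K_BS = 1, K_SB = 2, K_SS = 3, K_DS = 4, K_STATIC = 5 };

struct Contact {
  int i, j, kind;
  double lambda, sigma, depth;
  int dir; // +1 forming, -1 fading, 0 static (always on)
};

struct Anchor {
  int bead, wall;   // wall 0 = Z=0, 1 = Z=s
  double ax, ay;    // anchor coords in the wall frame (top: x minus shear)
  double lambda;
};

struct Sys {
  int n;
  std::vector<double> x, y, z;          // positions
  std::vector<double> r1, r2, r3, r4, r5; // scaled Taylor derivatives (3N each)
  double Lx, Ly, s, sprime, time;
  std::vector<Contact> reg;
  std::vector<Anchor> anch;
  // derived bookkeeping
  std::vector<double> bb_used, ss_used;
  std::vector<int> cys_bonded, anchored; // anchored: index into anch + 1, or 0
  std::unordered_set<long long> regset;
};

static long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Sys read_state(List st, const Topo& tp) {
  Sys s;
  NumericMatrix pos = st["pos"];
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  const char* dn[5] = {"r1", "r2", "r3", "r4", "r5"};
  std::vector<double>* dd[5] = {&s.r1, &s.r2, &s.r3, &s.r4, &s.r5};
  for (int k = 0; k < 5; ++k) {
    NumericMatrix m = st[dn[k]];
    dd[k]->resize(3 * s.n);
    for (int i = 0; i < s.n; ++i) {
      (*dd[k])[3 * i] = m(i, 0); (*dd[k])[3 * i + 1] = m(i, 1);
      (*dd[k])[3 * i + 2] = m(i, 2);
    }
  }
  NumericVector box = st["box"];
  s.Lx = box[0]; s.Ly = box[1]; s.s = box[2]; s.sprime = box[3];
  s.time = st["time"];
  List reg = st["reg"];
  IntegerVector ri = reg["i"], rj = reg["j"], rk = reg["kind"], rd = reg["dir"];
  NumericVector rl = reg["lambda"], rs = reg["sigma"], rp = reg["depth"];
  for (int k = 0; k < ri.size(); ++k) {
    Contact c{ri[k] - 1, rj[k] - 1, rk[k], rl[k], rs[k], rp[k], rd[k]};
    s.reg.push_back(c);
  }
  List an = st["anch"];
  IntegerVector ab = an["bead"], aw = an["wall"];
  NumericVector ax = an["ax"], ay = an["ay"], al = an["lambda"];
  for (int k = 0; k < ab.size(); ++k)
    s.anch.push_back(Anchor{ab[k] - 1, aw[k], ax[k], ay[k], al[k]});
  // bookkeeping
  s.bb_used.assign(s.n, 0.0); s.ss_used.assign(s.n, 0.0);
  s.cys_bonded.assign(s.n, 0); s.anchored.assign(s.n, 0);
  for (size_t k = 0; k < s.reg.size(); ++k) {
    const Contact& c = s.reg[k];
    s.regset.insert(pkey(c.i, c.j, s.n));
    switch (c.kind) {
    case K_BB: s.bb_used[c.i] += 1; s.bb_used[c.j] += 1; break;
    case K_BS: s.bb_used[c.i] += 1; s.ss_used[c.j] += 1; break;
    case K_SB: s.ss_used[c.i] += 1; s.bb_used[c.j] += 1; break;
    case K_SS: s.ss_used[c.i] += 1; s.ss_used[c.j] += 1; break;
    case K_DS: s.cys_bonded[c.i] = 1; s.cys_bonded[c.j] = 1; break;
    default: break; // static contacts do not consume dynamic slots
    }
  }
  for (size_t k = 0; k < s.anch.size(); ++k) s.anchored[s.anch[k].bead] = k + 1;
  (void)tp;
  return s;
}

static List write_state(const Sys& s) {
  NumericMatrix pos(s.n, 3), m1(s.n, 3), m2(s.n, 3), m3(s.n, 3), m4(s.n, 3),
      m5(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    pos(i, 0) = s.x[i]; pos(i, 1) = s.y[i]; pos(i, 2) = s.z[i];
    for (int d = 0; d < 3; ++d) {
      m1(i, d) = s.r1[3 * i + d]; m2(i, d) = s.r2[3 * i + d];
      m3(i, d) = s.r3[3 * i + d]; m4(i, d) = s.r4[3 * i + d];
      m5(i, d) = s.r5[3 * i + d];
    }
  }
  int nr = s.reg.size();
  IntegerVector ri(nr), rj(nr), rk(nr), rd(nr);
  NumericVector rl(nr), rs(nr), rp(nr);
  for (int k = 0; k < nr; ++k) {
    ri[k] = s.reg[k].i + 1; rj[k] = s.reg[k].j + 1; rk[k] = s.reg[k].kind;
    rd[k] = s.reg[k].dir; rl[k] = s.reg[k].lambda; rs[k] = s.reg[k].sigma;
    rp[k] = s.reg[k].depth;
  }
  int na = s.anch.size();
  IntegerVector ab(na), aw(na);
  NumericVector ax(na), ay(na), al(na);
  for (int k = 0; k < na; ++k) {
    ab[k] = s.anch[k].bead + 1; aw[k] = s.anch[k].wall; ax[k] = s.anch[k].ax;
    ay[k] = s.anch[k].ay; al[k] = s.anch[k].lambda;
  }
  return List::create(
      _["pos"] = pos, _["r1"] = m1, _["r2"] = m2, _["r3"] = m3, _["r4"] = m4,
      _["r5"] = m5,
      _["box"] = NumericVector::create(s.Lx, s.Ly, s.s, s.sprime),
      _["time"] = s.time,
      _["reg"] = List::create(_["i"] = ri, _["j"] = rj, _["kind"] = rk,
                              _["lambda"] = rl, _["dir"] = rd, _["sigma"] = rs,
                              _["depth"] = rp),
      _["anch"] = List::create(_["bead"] = ab, _["wall"] = aw, _["ax"] = ax,
                               _["ay"] = ay, _["lambda"] = al));
}

// ---------------------------------------------------------------------------
// elementary potentials -----------------------------------------------------

// truncated + shifted repulsive LJ, zero beyond r_o; linear continuation
// below cap_r so that forces stay finite during violent initial contacts
static inline void ev_term(double r, const Par& p, double& V, double& dV) {
  if (r >= p.r_o) { V = 0; dV = 0; return; }
  double rr = r < p.cap_r ? p.cap_r : r;
  double s6 = std::pow(p.sigma0 / rr, 6.0);
  V = 4 * s6 * s6 - 4 * s6 + 1;
  dV = (-48 * s6 * s6 + 24 * s6) / rr;
  if (r < p.cap_r) { V += dV * (r - p.cap_r); }
}

// full LJ with depth `depth` and minimum at SIX*sigma
static inline void lj_term(double r, double sigma, double depth, const Par& p,
                           double& V, double& dV) {
  double rr = r < p.cap_r ? p.cap_r : r;
  double s6 = std::pow(sigma / rr, 6.0);
  V = 4 * depth * (s6 * s6 - s6);
  dV = 4 * depth * (-12 * s6 * s6 + 6 * s6) / rr;
  if (r < p.cap_r) { V += dV * (r - p.cap_r); }
}

// Debye-Hueckel with distance-proportional relative permittivity
static inline void elec_term(double r, double qq, const Par& p, double& V,
                             double& dV) {
  if (r >= p.elec_cutoff || qq == 0) { V = 0; dV = 0; return; }
  double pref = p.coulomb * qq / p.perm_slope;
  double e = std::exp(-r / p.debye);
  V = pref * e / (r * r);
  dV = pref * e * (-2.0 / (r * r * r) - 1.0 / (p.debye * r * r));
}

// WCA split of the wall LJ (total depth wall_depth, minimum at wall_dmin):
// repulsive plane part (always on) and attractive anchor tail.
static inline void wall_rep(double d, const Par& p, double& V, double& dV) {
  if (d >= p.wall_dmin) { V = 0; dV = 0; return; }
  double sig = p.wall_dmin / SIX;
  double cap = 0.05;
  double dd = d < cap ? cap : d;
  double s6 = std::pow(sig / dd, 6.0);
  V = 4 * p.wall_depth * (s6 * s6 - s6) + p.wall_depth;
  dV = 4 * p.wall_depth * (-12 * s6 * s6 + 6 * s6) / dd;
  if (d < cap) V += dV * (d - cap);
}

static inline void wall_tail(double r, const Par& p, double& V, double& dV) {
  if (r < p.wall_dmin) { V = -p.wall_depth; dV = 0; return; }
  double sig = p.wall_dmin / SIX;
  double s6 = std::pow(sig / r, 6.0);
  V = 4 * p.wall_depth * (s6 * s6 - s6);
  dV = 4 * p.wall_depth * (-12 * s6 * s6 + 6 * s6) / r;
}

// ---------------------------------------------------------------------------
// local frames and contact classification -----------------------------------

struct Frames {
  std::vector<double> hx, hy, hz, sx, sy, sz; // binormal, sidechain direction
  std::vector<int> ok;
};

static inline void mimg(double& dx, double& dy, double Lx, double Ly) {
  dx -= Lx * std::round(dx / Lx);
  dy -= Ly * std::round(dy / Ly);
}

static void compute_frames(const Sys& s, const Topo& tp, Frames& fr) {
  int n = s.n;
  fr.hx.assign(n, 0); fr.hy.assign(n, 0); fr.hz.assign(n, 0);
  fr.sx.assign(n, 0); fr.sy.assign(n, 0); fr.sz.assign(n, 0);
  fr.ok.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    if (i == 0 || i == n - 1) continue;
    if (tp.chain[i - 1] != tp.chain[i] || tp.chain[i + 1] != tp.chain[i])
      continue;
    double ax = s.x[i] - s.x[i - 1], ay = s.y[i] - s.y[i - 1],
           az = s.z[i] - s.z[i - 1];
    double bx = s.x[i + 1] - s.x[i], by = s.y[i + 1] - s.y[i],
           bz = s.z[i + 1] - s.z[i];
    mimg(ax, ay, s.Lx, s.Ly); mimg(bx, by, s.Lx, s.Ly);
    double hx = ay * bz - az * by, hy = az * bx - ax * bz,
           hz = ax * by - ay * bx;
    double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    double bn = std::sqrt(bx * bx + by * by + bz * bz);
    if (hn < 1e-6 * an * bn) continue; // collinear: degenerate frame
    hx /= hn; hy /= hn; hz /= hn;
    // curvature normal: (b - a) orthogonalised against the local tangent
    double tx = ax + bx, ty = ay + by, tz = az + bz;
    double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
    tx /= tn; ty /= tn; tz /= tn;
    double cx = bx - ax, cy = by - ay, cz = bz - az;
    double ct = cx * tx + cy * ty + cz * tz;
    cx -= ct * tx; cy -= ct * ty; cz -= ct * tz;
    double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (cn < 1e-9) continue;
    // sidechain direction is minus the curvature normal
    fr.sx[i] = -cx / cn; fr.sy[i] = -cy / cn; fr.sz[i] = -cz / cn;
    fr.hx[i] = hx; fr.hy[i] = hy; fr.hz[i] = hz;
    fr.ok[i] = 1;
  }
}

// classify a candidate pair; returns kind or -1; fills sigma/depth
static int classify_pair(int i, int j, double r, double ux, double uy,
                         double uz, const Frames& fr, const Topo& tp,
                         const Par& p, double& sigma, double& depth) {
  if (!fr.ok[i] || !fr.ok[j]) return -1;
  double thr = p.align_thr;
  double hi = std::fabs(fr.hx[i] * ux + fr.hy[i] * uy + fr.hz[i] * uz);
  double hj = std::fabs(fr.hx[j] * ux + fr.hy[j] * uy + fr.hz[j] * uz);
  double si = fr.sx[i] * ux + fr.sy[i] * uy + fr.sz[i] * uz;
  double sj = -(fr.sx[j] * ux + fr.sy[j] * uy + fr.sz[j] * uz);
  bool bi = hi >= thr, bj = hj >= thr, ci = si >= thr, cj = sj >= thr;
  double dss = p.ss_min(tp.type[i], tp.type[j]);
  if (bi && bj && r < p.bb_min) {
    sigma = p.bb_min / SIX; depth = p.bb_multiplier; return K_BB;
  }
  if (ci && cj && r < dss) { sigma = dss / SIX; depth = p.ss_depth; return K_SS; }
  if (bi && cj && r < p.bs_min) {
    sigma = p.bs_min / SIX; depth = p.ss_depth; return K_BS;
  }
  if (ci && bj && r < p.bs_min) {
    sigma = p.bs_min / SIX; depth = p.ss_depth; return K_SB;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Verlet neighbour list -----------------------------------------------------

struct NbList {
  std::vector<int> pi, pj;
  std::vector<double> x0, y0, z0;
  double rlist;
  bool built = false;
};

static void build_nblist(const Sys& s, const Par& p, NbList& nb) {
  nb.rlist = p.nb_cutoff + p.skin;
  nb.pi.clear(); nb.pj.clear();
  double r2 = nb.rlist * nb.rlist;
  for (int i = 0; i < s.n; ++i)
    for (int j = i + 1; j < s.n; ++j) {
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      mimg(dx, dy, s.Lx, s.Ly);
      if (dx * dx + dy * dy + dz * dz < r2) { nb.pi.push_back(i); nb.pj.push_back(j); }
    }
  nb.x0 = s.x; nb.y0 = s.y; nb.z0 = s.z;
  nb.built = true;
}

static bool nblist_stale(const Sys& s, const Par& p, const NbList& nb) {
  if (!nb.built) return true;
  double lim = 0.25 * p.skin * p.skin; // (skin/2)^2
  for (int i = 0; i < s.n; ++i) {
    double dx = s.x[i] - nb.x0[i], dy = s.y[i] - nb.y0[i],
           dz = s.z[i] - nb.z0[i];
    mimg(dx, dy, s.Lx, s.Ly);
    if (dx * dx + dy * dy + dz * dz > lim) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// full force / energy evaluation --------------------------------------------

struct ForceOut {
  std::vector<double> fx, fy, fz;
  double E, e_bond, e_angle, e_dih, e_ev, e_elec, e_contact, e_wall;
  // force exerted BY the beads ON each wall (reaction): [wall][x,z]
  double wfx[2], wfz[2];
};

static void compute_forces(const Sys& s, const Topo& tp, const Par& p,
                           const NbList& nb, bool attraction, ForceOut& out) {
  int n = s.n;
  out.fx.assign(n, 0); out.fy.assign(n, 0); out.fz.assign(n, 0);
  out.e_bond = out.e_angle = out.e_dih = out.e_ev = out.e_elec = 0;
  out.e_contact = out.e_wall = 0;
  out.wfx[0] = out.wfx[1] = out.wfz[0] = out.wfz[1] = 0;

  // bonds ---------------------------------------------------------------
  for (int i = 0; i + 1 < n; ++i) {
    if (tp.chain[i] != tp.chain[i + 1]) continue;
    double dx = s.x[i + 1] - s.x[i], dy = s.y[i + 1] - s.y[i],
           dz = s.z[i + 1] - s.z[i];
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - p.r_b;
    out.e_bond += p.k_bond * d * d;
    double f = -2 * p.k_bond * d / r; // dV/dr / r with sign for force
    out.fx[i] -= f * dx; out.fy[i] -= f * dy; out.fz[i] -= f * dz;
    out.fx[i + 1] += f * dx; out.fy[i + 1] += f * dy; out.fz[i + 1] += f * dz;
  }

  // bond angles ---------------------------------------------------------
  for (int j = 1; j + 1 < n; ++j) {
    if (tp.chain[j - 1] != tp.chain[j] || tp.chain[j + 1] != tp.chain[j])
      continue;
    int cl = tp.cls[j];
    double ux = s.x[j - 1] - s.x[j], uy = s.y[j - 1] - s.y[j],
           uz = s.z[j - 1] - s.z[j];
    double wx = s.x[j + 1] - s.x[j], wy = s.y[j + 1] - s.y[j],
           wz = s.z[j + 1] - s.z[j];
    mimg(ux, uy, s.Lx, s.Ly); mimg(wx, wy, s.Lx, s.Ly);
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
    double c = (ux * wx + uy * wy + uz * wz) / (un * wn);
    if (c > 1) c = 1; if (c < -1) c = -1;
    double th = std::acos(c);
    double st = std::sqrt(1 - c * c);
    if (st < 1e-8) st = 1e-8;
    double dVdt = 2 * p.ka[cl] * (th - p.th0[cl]);
    out.e_angle += p.ka[cl] * (th - p.th0[cl]) * (th - p.th0[cl]);
    // dtheta/dri = (cos(th) u_hat - w_hat) / (|u| sin th)
    double gix = (c * ux / un - wx / wn) / (un * st);
    double giy = (c * uy / un - wy / wn) / (un * st);
    double giz = (c * uz / un - wz / wn) / (un * st);
    double gkx = (c * wx / wn - ux / un) / (wn * st);
    double gky = (c * wy / wn - uy / un) / (wn * st);
    double gkz = (c * wz / wn - uz / un) / (wn * st);
    out.fx[j - 1] -= dVdt * gix; out.fy[j - 1] -= dVdt * giy;
    out.fz[j - 1] -= dVdt * giz;
    out.fx[j + 1] -= dVdt * gkx; out.fy[j + 1] -= dVdt * gky;
    out.fz[j + 1] -= dVdt * gkz;
    out.fx[j] += dVdt * (gix + gkx); out.fy[j] += dVdt * (giy + gky);
    out.fz[j] += dVdt * (giz + gkz);
  }

  // dihedrals -----------------------------------------------------------
  for (int i = 0; i + 3 < n; ++i) {
    if (tp.chain[i] != tp.chain[i + 3]) continue;
    int cl = tp.cls[i + 2];
    double b1x = s.x[i + 1] - s.x[i], b1y = s.y[i + 1] - s.y[i],
           b1z = s.z[i + 1] - s.z[i];
    double b2x = s.x[i + 2] - s.x[i + 1], b2y = s.y[i + 2] - s.y[i + 1],
           b2z = s.z[i + 2] - s.z[i + 1];
    double b3x = s.x[i + 3] - s.x[i + 2], b3y = s.y[i + 3] - s.y[i + 2],
           b3z = s.z[i + 3] - s.z[i + 2];
    mimg(b1x, b1y, s.Lx, s.Ly); mimg(b2x, b2y, s.Lx, s.Ly);
    mimg(b3x, b3y, s.Lx, s.Ly);
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
           n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
           n2z = b2x * b3y - b2y * b3x;
    double n1s = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2s = n2x * n2x + n2y * n2y + n2z * n2z;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1s < 1e-12 || n2s < 1e-12) continue;
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
           mz = n1x * n2y - n1y * n2x;
    double sy = (mx * b2x + my * b2y + mz * b2z) / b2n;
    double cx_ = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(sy, cx_);
    double V = p.kd1[cl] * (1 + std::cos(phi - p.p1[cl])) +
               p.kd3[cl] * (1 + std::cos(3 * phi - p.p3[cl]));
    double dVdphi = -p.kd1[cl] * std::sin(phi - p.p1[cl]) -
                    3 * p.kd3[cl] * std::sin(3 * phi - p.p3[cl]);
    out.e_dih += V;
    // gradient of phi wrt the outer beads, then the chain-rule identities
    double gix = -b2n / n1s * n1x, giy = -b2n / n1s * n1y,
           giz = -b2n / n1s * n1z;
    double glx = b2n / n2s * n2x, gly = b2n / n2s * n2y,
           glz = b2n / n2s * n2z;
    double tt = (b1x * b2x + b1y * b2y + b1z * b2z) / (b2n * b2n);
    double ss = (b3x * b2x + b3y * b2y + b3z * b2z) / (b2n * b2n);
    double gjx = -(1 + tt) * gix + ss * glx;
    double gjy = -(1 + tt) * giy + ss * gly;
    double gjz = -(1 + tt) * giz + ss * glz;
    double gkx = tt * gix - (1 + ss) * glx;
    double gky = tt * giy - (1 + ss) * gly;
    double gkz = tt * giz - (1 + ss) * glz;
    double fix = -dVdphi * gix, fiy = -dVdphi * giy, fiz = -dVdphi * giz;
    double fjx = -dVdphi * gjx, fjy = -dVdphi * gjy, fjz = -dVdphi * gjz;
    double fkx = -dVdphi * gkx, fky = -dVdphi * gky, fkz = -dVdphi * gkz;
    double flx = -dVdphi * glx, fly = -dVdphi * gly, flz = -dVdphi * glz;
    out.fx[i] += fix; out.fy[i] += fiy; out.fz[i] += fiz;
    out.fx[i + 1] += fjx; out.fy[i + 1] += fjy; out.fz[i + 1] += fjz;
    out.fx[i + 2] += fkx; out.fy[i + 2] += fky; out.fz[i + 2] += fkz;
    out.fx[i + 3] += flx; out.fy[i + 3] += fly; out.fz[i + 3] += flz;
  }

  // non-bonded pairs (excluded volume + electrostatics) ------------------
  for (size_t k = 0; k < nb.pi.size(); ++k) {
    int i = nb.pi[k], j = nb.pj[k];
    bool bonded = (tp.chain[i] == tp.chain[j]) && (j - i == 1);
    if (bonded) continue;
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    mimg(dx, dy, s.Lx, s.Ly);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > p.nb_cutoff * p.nb_cutoff) continue;
    double r = std::sqrt(r2);
    bool inreg = s.regset.count(pkey(i, j, n)) > 0;
    double V = 0, dV = 0;
    if (!inreg && r < p.r_o) {
      ev_term(r, p, V, dV);
      out.e_ev += V;
    }
    if (p.any_charges) {
      double qq = tp.charge[i] * tp.charge[j];
      if (qq != 0 && r < p.elec_cutoff) {
        double Ve, dVe;
        elec_term(r, qq, p, Ve, dVe);
        out.e_elec += Ve; V += Ve; dV += dVe;
      }
    }
    if (dV != 0) {
      double f = -dV / r;
      out.fx[i] += f * dx; out.fy[i] += f * dy; out.fz[i] += f * dz;
      out.fx[j] -= f * dx; out.fy[j] -= f * dy; out.fz[j] -= f * dz;
    }
  }

  // contacts: blend (1-lambda) * excluded volume + lambda * attractive LJ
  for (size_t k = 0; k < s.reg.size(); ++k) {
    const Contact& c = s.reg[k];
    double dx = s.x[c.i] - s.x[c.j], dy = s.y[c.i] - s.y[c.j],
           dz = s.z[c.i] - s.z[c.j];
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double Ve, dVe, Va, dVa;
    ev_term(r, p, Ve, dVe);
    lj_term(r, c.sigma, c.depth, p, Va, dVa);
    double V = (1 - c.lambda) * Ve + c.lambda * Va;
    double dV = (1 - c.lambda) * dVe + c.lambda * dVa;
    out.e_contact += V;
    double f = -dV / r;
    out.fx[c.i] += f * dx; out.fy[c.i] += f * dy; out.fz[c.i] += f * dz;
    out.fx[c.j] -= f * dx; out.fy[c.j] -= f * dy; out.fz[c.j] -= f * dz;
  }

  // walls ----------------------------------------------------------------
  for (int i = 0; i < n; ++i) {
    // repulsive plane part, both walls, always on
    double d0 = s.z[i], d1 = s.s - s.z[i];
    double V, dV;
    wall_rep(d0, p, V, dV);
    out.e_wall += V;
    out.fz[i] += -dV;      // force on bead along +z
    out.wfz[0] -= -dV;     // reaction on bottom wall
    wall_rep(d1, p, V, dV);
    out.e_wall += V;
    out.fz[i] += dV;       // d(d1)/dz = -1
    out.wfz[1] -= dV;
  }
  for (size_t k = 0; k < s.anch.size(); ++k) {
    const Anchor& a = s.anch[k];
    double axw = a.wall == 1 ? a.ax + s.sprime : a.ax;
    double azw = a.wall == 1 ? s.s : 0.0;
    double dx = s.x[a.bead] - axw, dy = s.y[a.bead] - a.ay,
           dz = s.z[a.bead] - azw;
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double V, dV;
    wall_tail(r, p, V, dV);
    V *= a.lambda; dV *= a.lambda;
    out.e_wall += V;
    double f = -dV / r;
    out.fx[a.bead] += f * dx; out.fy[a.bead] += f * dy;
    out.fz[a.bead] += f * dz;
    out.wfx[a.wall] -= f * dx;
    out.wfz[a.wall] -= f * dz;
  }
  (void)attraction;
  out.E = out.e_bond + out.e_angle + out.e_dih + out.e_ev + out.e_elec +
          out.e_contact + out.e_wall;
}

// ---------------------------------------------------------------------------
// registry / anchor updates --------------------------------------------------

static void update_registry(Sys& s, const Topo& tp, const Par& p,
                            const NbList& nb, const Frames& fr) {
  int n = s.n;
  double dl = p.dt / p.t_switch;
  // 1. evolve existing records
  for (size_t k = 0; k < s.reg.size(); ++k) {
    Contact& c = s.reg[k];
    if (c.kind == K_STATIC) continue; // static contacts never switch off
    double dx = s.x[c.i] - s.x[c.j], dy = s.y[c.i] - s.y[c.j],
           dz = s.z[c.i] - s.z[c.j];
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double rf = p.f_cut * c.sigma * SIX; // breaking distance f * r_min
    if (c.dir > 0 && r > rf) c.dir = -1;
    else if (c.dir < 0 && r <= c.sigma * SIX) c.dir = +1; // re-forms in range
    c.lambda += c.dir > 0 ? dl : -dl;
    if (c.lambda > 1) c.lambda = 1;
  }
  // 2. remove dead records (lambda ran down to zero)
  std::vector<Contact> keep;
  keep.reserve(s.reg.size());
  bool removed = false;
  for (size_t k = 0; k < s.reg.size(); ++k) {
    Contact& c = s.reg[k];
    if (c.kind != K_STATIC && c.lambda <= 0) {
      removed = true;
      switch (c.kind) {
      case K_BB: s.bb_used[c.i] -= 1; s.bb_used[c.j] -= 1; break;
      case K_BS: s.bb_used[c.i] -= 1; s.ss_used[c.j] -= 1; break;
      case K_SB: s.ss_used[c.i] -= 1; s.bb_used[c.j] -= 1; break;
      case K_SS: s.ss_used[c.i] -= 1; s.ss_used[c.j] -= 1; break;
      case K_DS: s.cys_bonded[c.i] = 0; s.cys_bonded[c.j] = 0; break;
      }
      s.regset.erase(pkey(c.i, c.j, n));
    } else keep.push_back(c);
  }
  if (removed) s.reg.swap(keep);
  else s.reg = keep;
  // 3. scan for new contacts among neighbour pairs
  for (size_t k = 0; k < nb.pi.size(); ++k) {
    int i = nb.pi[k], j = nb.pj[k];
    if (tp.chain[i] == tp.chain[j] && j - i < 3) continue; // incl. i,i+2
    if (s.regset.count(pkey(i, j, n))) continue;
    double dx = s.x[j] - s.x[i], dy = s.y[j] - s.y[i], dz = s.z[j] - s.z[i];
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > p.nb_cutoff) continue;
    // disulfide bridges take precedence for free cysteine pairs
    if (tp.is_cys[i] && tp.is_cys[j] && !s.cys_bonded[i] && !s.cys_bonded[j] &&
        r < p.r_min_SS) {
      Contact c{i, j, K_DS, dl, p.r_min_SS / SIX, p.SS_depth, +1};
      s.reg.push_back(c);
      s.regset.insert(pkey(i, j, n));
      s.cys_bonded[i] = s.cys_bonded[j] = 1;
      continue;
    }
    double ux = dx / r, uy = dy / r, uz = dz / r;
    double sigma, depth;
    int kind = classify_pair(i, j, r, ux, uy, uz, fr, tp, p, sigma, depth);
    if (kind < 0) continue;
    // capacity limits
    bool okcap = true;
    switch (kind) {
    case K_BB:
      okcap = s.bb_used[i] < tp.bb_cap[i] && s.bb_used[j] < tp.bb_cap[j];
      break;
    case K_BS:
      okcap = s.bb_used[i] < tp.bb_cap[i] && s.ss_used[j] < tp.ss_cap[j];
      break;
    case K_SB:
      okcap = s.ss_used[i] < tp.ss_cap[i] && s.bb_used[j] < tp.bb_cap[j];
      break;
    case K_SS:
      okcap = s.ss_used[i] < tp.ss_cap[i] && s.ss_used[j] < tp.ss_cap[j];
      break;
    }
    if (!okcap) continue;
    Contact c{i, j, kind, dl, sigma, depth, +1};
    s.reg.push_back(c);
    s.regset.insert(pkey(i, j, n));
    switch (kind) {
    case K_BB: s.bb_used[i] += 1; s.bb_used[j] += 1; break;
    case K_BS: s.bb_used[i] += 1; s.ss_used[j] += 1; break;
    case K_SB: s.ss_used[i] += 1; s.bb_used[j] += 1; break;
    case K_SS: s.ss_used[i] += 1; s.ss_used[j] += 1; break;
    }
  }
}

static void update_anchors(Sys& s, const Par& p, bool attraction) {
  double dl = p.dt / p.t_switch;
  // evolve / detach existing anchors
  std::vector<Anchor> keep;
  keep.reserve(s.anch.size());
  bool removed = false;
  for (size_t k = 0; k < s.anch.size(); ++k) {
    Anchor a = s.anch[k];
    double axw = a.wall == 1 ? a.ax + s.sprime : a.ax;
    double azw = a.wall == 1 ? s.s : 0.0;
    double dx = s.x[a.bead] - axw, dy = s.y[a.bead] - a.ay,
           dz = s.z[a.bead] - azw;
    mimg(dx, dy, s.Lx, s.Ly);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > p.wall_detach) { // detached: interaction centre disappears
      s.anchored[a.bead] = 0;
      removed = true;
      continue;
    }
    a.lambda += dl;
    if (a.lambda > 1) a.lambda = 1;
    keep.push_back(a);
  }
  s.anch.swap(keep);
  if (removed)
    for (size_t k = 0; k < s.anch.size(); ++k)
      s.anchored[s.anch[k].bead] = k + 1;
  if (!attraction) return;
  // new attachments
  for (int i = 0; i < s.n; ++i) {
    if (s.anchored[i]) continue;
    double d0 = s.z[i], d1 = s.s - s.z[i];
    int wall = -1;
    if (d0 < p.wall_dmin && d0 <= d1) wall = 0;
    else if (d1 < p.wall_dmin) wall = 1;
    if (wall < 0) continue;
    double ax = wall == 1 ? s.x[i] - s.sprime : s.x[i];
    ax -= s.Lx * std::floor(ax / s.Lx);
    Anchor a{i, wall, ax, s.y[i], dl};
    s.anch.push_back(a);
    s.anchored[i] = s.anch.size();
  }
}

// counts of "active" contacts: dynamic records with lambda >= 0.5 plus
// static map contacts currently within the r < f*sigma*2^(1/6) range
static void count_contacts(const Sys& s, const Topo& tp, const Par& p,
                           int& ntot, int& ninter) {
  ntot = 0; ninter = 0;
  for (size_t k = 0; k < s.reg.size(); ++k) {
    const Contact& c = s.reg[k];
    bool active;
    if (c.kind == K_STATIC) {
      double dx = s.x[c.i] - s.x[c.j], dy = s.y[c.i] - s.y[c.j],
             dz = s.z[c.i] - s.z[c.j];
      mimg(dx, dy, s.Lx, s.Ly);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      active = r < p.f_cut * c.sigma * SIX;
    } else active = c.lambda >= 0.5;
    if (active) {
      ++ntot;
      if (tp.chain[c.i] != tp.chain[c.j]) ++ninter;
    }
  }
}

// ---------------------------------------------------------------------------
// exported: single-shot energy/forces ----------------------------------------

// [[Rcpp::export]]
List cpp_energy_forces(List state, List topo, List par) {
  Par p = read_par(par);
  Topo tp = read_topo(topo);
  Sys s = read_state(state, tp);
  NbList nb;
  build_nblist(s, p, nb);
  ForceOut out;
  compute_forces(s, tp, p, nb, true, out);
  NumericMatrix F(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    F(i, 0) = out.fx[i]; F(i, 1) = out.fy[i]; F(i, 2) = out.fz[i];
  }
  return List::create(
      _["energy"] = out.E,
      _["terms"] = NumericVector::create(
          _["bond"] = out.e_bond, _["angle"] = out.e_angle,
          _["dihedral"] = out.e_dih, _["ev"] = out.e_ev,
          _["elec"] = out.e_elec, _["contact"] = out.e_contact,
          _["wall"] = out.e_wall),
      _["forces"] = F,
      _["wall_fx"] = NumericVector::create(out.wfx[0], out.wfx[1]),
      _["wall_fz"] = NumericVector::create(out.wfz[0], out.wfz[1]));
}

// ---------------------------------------------------------------------------
// exported: run one protocol stage -------------------------------------------

// Gear 5th-order corrector coefficients (position-dependent forces; the
// Langevin friction + noise are applied as an exact Ornstein-Uhlenbeck
// velocity update after the corrector, so the corrected force is
// conservative only)
static const double GA0 = 3.0 / 16, GA1 = 251.0 / 360, GA3 = 11.0 / 18,
                    GA4 = 1.0 / 6, GA5 = 1.0 / 60;

// [[Rcpp::export]]
List cpp_run_stage(List state, List topo, List par, List stage) {
  Par p = read_par(par);
  Topo tp = read_topo(topo);
  Sys s = read_state(state, tp);
  int nsteps = stage["nsteps"];
  int motion = stage["motion"];
  bool attraction = stage["attraction"];
  bool contact_update = stage["contact_update"];
  bool freeze = stage["freeze"];
  int record_stride = stage["record_stride"];
  int snapshot_stride = stage["snapshot_stride"];
  double m_rate = stage["m_rate"], m_sspeed = stage["m_sspeed"],
         m_xspeed = stage["m_xspeed"], m_A = stage["m_A"],
         m_omega = stage["m_omega"], m_s0ref = stage["m_s0ref"];
  double seed = stage["seed"];

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  int n = s.n;
  double dt = p.dt;
  // exact OU coefficients: v <- c1 v + c2 xi each step
  double c1 = std::exp(-p.gamma * dt / p.mass);
  double c2 = p.temperature > 0
                  ? std::sqrt(p.temperature / p.mass * (1.0 - c1 * c1))
                  : 0.0;
  double hdt2 = dt * dt / 2.0;

  NbList nb;
  Frames fr;
  ForceOut out;

  int nrec = record_stride > 0 ? nsteps / record_stride : 0;
  NumericMatrix rec(nrec, 9);
  int irec = 0;
  double accfx0 = 0, accfz0 = 0, accfx1 = 0, accfz1 = 0;
  int accn = 0;

  List snaps;
  std::vector<double> snap_t;

  double s_start = s.s, sprime_start = s.sprime;
  double t_loc = 0;

  for (int step = 0; step < nsteps; ++step) {
    // --- wall / box motion over [t_loc, t_loc + dt] -----------------------
    double t1 = t_loc + dt;
    switch (motion) {
    case 1: { // isotropic compression, relative rate m_rate per tau
      double f0 = 1.0 - m_rate * t_loc, f1 = 1.0 - m_rate * t1;
      double sc = f1 / f0;
      s.Lx *= sc; s.Ly *= sc; s.s = s_start * f1;
      for (int i = 0; i < n; ++i) {
        s.x[i] *= sc; s.y[i] *= sc;
        s.r1[3 * i] *= sc; s.r1[3 * i + 1] *= sc;
        s.r2[3 * i] *= sc; s.r2[3 * i + 1] *= sc;
        s.r3[3 * i] *= sc; s.r3[3 * i + 1] *= sc;
        s.r4[3 * i] *= sc; s.r4[3 * i + 1] *= sc;
        s.r5[3 * i] *= sc; s.r5[3 * i + 1] *= sc;
      }
      nb.built = false;
      break;
    }
    case 2: s.s = s_start + m_sspeed * t1; break;
    case 3: s.s = m_s0ref - m_A * std::cos(m_omega * t1); break;
    case 4: s.sprime = -m_A * std::cos(m_omega * t1); break;
    case 5: s.sprime = sprime_start + m_xspeed * t1; break;
    default: break;
    }

    if (!freeze) {
      // --- Gear predictor ------------------------------------------------
      std::vector<double> x_old;
      for (int i = 0; i < n; ++i) {
        double* r1 = &s.r1[3 * i]; double* r2 = &s.r2[3 * i];
        double* r3 = &s.r3[3 * i]; double* r4 = &s.r4[3 * i];
        double* r5 = &s.r5[3 * i];
        double px[3] = {s.x[i], s.y[i], s.z[i]};
        for (int d = 0; d < 3; ++d) {
          double np = px[d] + r1[d] + r2[d] + r3[d] + r4[d] + r5[d];
          r1[d] += 2 * r2[d] + 3 * r3[d] + 4 * r4[d] + 5 * r5[d];
          r2[d] += 3 * r3[d] + 6 * r4[d] + 10 * r5[d];
          r3[d] += 4 * r4[d] + 10 * r5[d];
          r4[d] += 5 * r5[d];
          px[d] = np;
        }
        s.x[i] = px[0]; s.y[i] = px[1]; s.z[i] = px[2];
      }
      if (nblist_stale(s, p, nb)) build_nblist(s, p, nb);
      compute_forces(s, tp, p, nb, attraction, out);
      // --- Gear corrector with Langevin friction + noise ------------------
      double maxcor = 0;
      for (int i = 0; i < n; ++i) {
        double* r1 = &s.r1[3 * i]; double* r2 = &s.r2[3 * i];
        double* r3 = &s.r3[3 * i]; double* r4 = &s.r4[3 * i];
        double* r5 = &s.r5[3 * i];
        double fc[3] = {out.fx[i], out.fy[i], out.fz[i]};
        double px[3] = {s.x[i], s.y[i], s.z[i]};
        for (int d = 0; d < 3; ++d) {
          double acc = fc[d] / p.mass;
          double delta = hdt2 * acc - r2[d];
          px[d] += GA0 * delta;
          r1[d] += GA1 * delta;
          r2[d] += delta;
          r3[d] += GA3 * delta;
          r4[d] += GA4 * delta;
          r5[d] += GA5 * delta;
          if (std::fabs(delta) > maxcor) maxcor = std::fabs(delta);
          // Ornstein-Uhlenbeck thermostat step on the velocity
          if (c1 != 1.0 || c2 > 0) {
            double v = c1 * (r1[d] / dt);
            if (c2 > 0) v += c2 * gauss(rng);
            r1[d] = v * dt;
          }
        }
        s.x[i] = px[0]; s.y[i] = px[1]; s.z[i] = px[2];
        // wrap X/Y
        s.x[i] -= s.Lx * std::floor(s.x[i] / s.Lx);
        s.y[i] -= s.Ly * std::floor(s.y[i] / s.Ly);
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
            !std::isfinite(s.z[i]))
          stop("non-finite coordinates at t = %f", s.time);
      }
      if (maxcor > 0.5 * p.r_o)
        stop("unstable step: displacement correction %f nm exceeds %f nm",
             maxcor, 0.5 * p.r_o);
    } else if (record_stride > 0 || contact_update) {
      if (nblist_stale(s, p, nb)) build_nblist(s, p, nb);
      if (record_stride > 0) compute_forces(s, tp, p, nb, attraction, out);
    }

    // --- dynamic contacts and wall anchors --------------------------------
    if (contact_update) {
      if (nblist_stale(s, p, nb)) build_nblist(s, p, nb);
      compute_frames(s, tp, fr);
      update_registry(s, tp, p, nb, fr);
      update_anchors(s, p, attraction);
    }

    t_loc = t1;
    s.time += dt;

    // --- recording ---------------------------------------------------------
    if (record_stride > 0) {
      accfx0 += out.wfx[0]; accfz0 += out.wfz[0];
      accfx1 += out.wfx[1]; accfz1 += out.wfz[1];
      ++accn;
      if ((step + 1) % record_stride == 0 && irec < nrec) {
        int ntot, ninter;
        count_contacts(s, tp, p, ntot, ninter);
        rec(irec, 0) = s.time; rec(irec, 1) = s.s; rec(irec, 2) = s.sprime;
        rec(irec, 3) = accfx0 / accn; rec(irec, 4) = accfz0 / accn;
        rec(irec, 5) = accfx1 / accn; rec(irec, 6) = accfz1 / accn;
        rec(irec, 7) = ntot; rec(irec, 8) = ninter;
        ++irec;
        accfx0 = accfz0 = accfx1 = accfz1 = 0; accn = 0;
      }
    }
    if (snapshot_stride > 0 && (step + 1) % snapshot_stride == 0) {
      NumericMatrix ps(n, 3);
      for (int i = 0; i < n; ++i) {
        ps(i, 0) = s.x[i]; ps(i, 1) = s.y[i]; ps(i, 2) = s.z[i];
      }
      snaps.push_back(ps);
      snap_t.push_back(s.time);
    }
  }

  colnames(rec) = CharacterVector::create("time", "s", "sprime", "fx_bottom",
                                          "fz_bottom", "fx_top", "fz_top",
                                          "n_contacts", "n_inter");
  return List::create(_["state"] = write_state(s), _["records"] = rec,
                      _["snapshots"] = snaps, _["snap_times"] = wrap(snap_t));
}

// ---------------------------------------------------------------------------
// exported: brute-force candidate count (oracle support) ---------------------

// [[Rcpp::export]]
List cpp_frames(List state, List topo) {
  Topo tp = read_topo(topo);
  Sys s = read_state(state, tp);
  Frames fr;
  compute_frames(s, tp, fr);
  int n = s.n;
  NumericMatrix H(n, 3), S(n, 3);
  IntegerVector ok(n);
  for (int i = 0; i < n; ++i) {
    H(i, 0) = fr.hx[i]; H(i, 1) = fr.hy[i]; H(i, 2) = fr.hz[i];
    S(i, 0) = fr.sx[i]; S(i, 1) = fr.sy[i]; S(i, 2) = fr.sz[i];
    ok[i] = fr.ok[i];
  }
  return List::create(_["h"] = H, _["side"] = S, _["ok"] = ok);
}
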