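// Simulation core: force field, constrained Langevin velocity-Verlet,
// and geometric topology measures for the torsional bead-spring DNA model.
//
// Bead layout: [M_0..M_{nm-1}] [A_0..A_{nb-1}] [P_0..P_{nb-1}]
// A_k sits at the midpoint of bond k; P_k at unit offset perpendicular to it.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925287;

// ------------------------------------------------------------------ RNG ----
// xoshiro256++ with splitmix64 seeding; normals via 128-layer ziggurat.
struct RNG {
  uint64_t s[4];
  // ziggurat tables (per-instance; cheap to build)
  uint32_t kn[128];
  double wn[128], fn[128];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x1ULL;
    zig_init();
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (double)(next() >> 11) * 1.1102230246251565e-16; }
  inline double unif_open() { double u; do { u = unif(); } while (u <= 0.0); return u; }

  void zig_init() {
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3, m1 = 2147483648.0;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double norm() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next();
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // fixup
      const double r = 3.442619855899;
      if (iz == 0) {
        double x, y;
        do { x = -std::log(unif_open()) / r; y = -std::log(unif_open()); } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x)) return x;
    }
  }
};

// ---------------------------------------------------------------- system ----
struct V3 { double x, y, z; };
static inline V3 vsub(const V3&a, const V3&b){ return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 vadd(const V3&a, const V3&b){ return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline V3 vscale(const V3&a, double s){ return {a.x*s, a.y*s, a.z*s}; }
static inline double vdot(const V3&a, const V3&b){ return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 vcross(const V3&a, const V3&b){
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vnorm(const V3&a){ return std::sqrt(vdot(a,a)); }

struct Chain { int first; int n_units; bool circular; int bond0; int nbonds; int jun0; int njun; };

struct Sys {
  int nm = 0, nb = 0, nj = 0, na = 0, N = 0;
  std::vector<Chain> chains;
  std::vector<int> bond_a, bond_b;          // per bond: M indices
  std::vector<int> jun_b1, jun_b2;          // per junction: bond indices
  std::vector<int> jun_enabled;
  std::vector<double> jun_phase;            // dynamic for active swivels
  std::vector<int> jun_active;
  std::vector<double> jun_rate, jun_sign;
  std::vector<int> ang_i, ang_j, ang_k;     // bending triples
  std::vector<double> ang_K;
  std::vector<double> charge;               // per M bead
  std::vector<int> gap;                     // per M bead 0/1
  int topoiii = 0, topoiii_dh = 0;
  std::unordered_set<int64_t> excl;         // nonbonded exclusions among M

  // params
  double sigma_ex, lB, kappa, dh_cut, Kd;
  double fK, fR0, fr0;
  double kT, gM, gP, gA, mass;
  double wca_cut2;

  // DH cubic-Hermite table in r (per unit q_i q_j)
  std::vector<double> dhU, dhG;   // value and derivative at nodes
  double dh_rmin, dh_dr; int dh_n;

  inline int64_t pkey(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (int64_t)i * 1000000 + j;
  }
  inline bool excluded(int i, int j) const { return excl.count(pkey(i, j)) > 0; }

  void build_dh_table() {
    dh_n = 2048; dh_rmin = 0.05; dh_dr = (dh_cut - dh_rmin) / (dh_n - 1);
    dhU.resize(dh_n); dhG.resize(dh_n);
    for (int i = 0; i < dh_n; i++) {
      double r = dh_rmin + i * dh_dr;
      double e = std::exp(-kappa * r);
      dhU[i] = lB * e / r;                         // per eps and per q_i q_j
      dhG[i] = -lB * e * (kappa * r + 1.0) / (r * r);
    }
  }
  // cubic Hermite; returns U(r), dU/dr (exact derivative of the interpolant)
  inline void dh_eval(double r, double &U, double &dU) const {
    if (r >= dh_cut) { U = 0; dU = 0; return; }
    double rr = r < dh_rmin ? dh_rmin : r;
    double t = (rr - dh_rmin) / dh_dr;
    int i = (int)t; if (i > dh_n - 2) i = dh_n - 2;
    t -= i;
    double h = dh_dr;
    double p0 = dhU[i], p1 = dhU[i + 1], m0 = dhG[i] * h, m1 = dhG[i + 1] * h;
    double t2 = t * t, t3 = t2 * t;
    U = (2*t3 - 3*t2 + 1) * p0 + (t3 - 2*t2 + t) * m0 + (-2*t3 + 3*t2) * p1 + (t3 - t2) * m1;
    dU = ((6*t2 - 6*t) * p0 + (3*t2 - 4*t + 1) * m0 + (-6*t2 + 6*t) * p1 + (3*t2 - 2*t) * m1) / h;
    if (r < dh_rmin) { /* linear continuation below rmin */
      double U0, dU0; // value at rmin
      U0 = dhU[0]; dU0 = dhG[0];
      U = U0 + dU0 * (r - dh_rmin); dU = dU0;
    }
  }
};

static Sys parse_sys(const List &topo, const List &params) {
  Sys S;
  S.nm = as<int>(topo["n_m"]);
  IntegerMatrix bonds = topo["bonds"];
  S.nb = bonds.nrow();
  S.bond_a.resize(S.nb); S.bond_b.resize(S.nb);
  for (int k = 0; k < S.nb; k++) { S.bond_a[k] = bonds(k,0); S.bond_b[k] = bonds(k,1); }
  IntegerMatrix jun = topo["junctions"];
  S.nj = jun.nrow();
  S.jun_b1.resize(S.nj); S.jun_b2.resize(S.nj);
  for (int j = 0; j < S.nj; j++) { S.jun_b1[j] = jun(j,0); S.jun_b2[j] = jun(j,1); }
  S.jun_enabled = as<std::vector<int> >(topo["jun_enabled"]);
  S.jun_phase   = as<std::vector<double> >(topo["jun_phase"]);
  S.jun_active  = as<std::vector<int> >(topo["jun_active"]);
  S.jun_rate    = as<std::vector<double> >(topo["jun_rate"]);
  S.jun_sign    = as<std::vector<double> >(topo["jun_sign"]);
  IntegerMatrix ang = topo["angles"];
  S.na = ang.nrow();
  S.ang_i.resize(S.na); S.ang_j.resize(S.na); S.ang_k.resize(S.na);
  for (int a = 0; a < S.na; a++) { S.ang_i[a]=ang(a,0); S.ang_j[a]=ang(a,1); S.ang_k[a]=ang(a,2); }
  S.ang_K  = as<std::vector<double> >(topo["angle_k"]);
  S.charge = as<std::vector<double> >(topo["charge"]);
  S.gap    = as<std::vector<int> >(topo["gap"]);
  S.topoiii    = as<int>(topo["topoiii"]);
  S.topoiii_dh = as<int>(topo["topoiii_dh"]);
  List chl = topo["chains"];
  for (int c = 0; c < chl.size(); c++) {
    List ch = chl[c];
    Chain C;
    C.first = as<int>(ch["first"]); C.n_units = as<int>(ch["n_units"]);
    C.circular = as<bool>(ch["circular"]);
    C.bond0 = as<int>(ch["bond0"]); C.nbonds = as<int>(ch["nbonds"]);
    C.jun0 = as<int>(ch["jun0"]); C.njun = as<int>(ch["njun"]);
    S.chains.push_back(C);
  }
  // exclusions: bonded pairs plus any extra pairs supplied
  for (int k = 0; k < S.nb; k++) S.excl.insert(S.pkey(S.bond_a[k], S.bond_b[k]));
  if (topo.containsElementNamed("excl_pairs")) {
    IntegerMatrix ep = topo["excl_pairs"];
    for (int k = 0; k < ep.nrow(); k++) S.excl.insert(S.pkey(ep(k,0), ep(k,1)));
  }
  S.N = S.nm + 2 * S.nb;

  S.sigma_ex = as<double>(params["sigma_ex"]);
  S.lB    = as<double>(params["bjerrum_length"]);
  S.kappa = as<double>(params["debye_kappa"]);
  S.dh_cut = as<double>(params["dh_cutoff"]);
  S.Kd    = as<double>(params["dihedral_constant"]);
  List fe = params["fene"];
  S.fK  = as<double>(fe["spring_constant"]);
  S.fR0 = as<double>(fe["max_extension"]);
  S.fr0 = as<double>(fe["rest_length"]);
  S.kT  = as<double>(params["epsilon"]);
  S.gM  = as<double>(params["drag_M"]);
  S.gP  = as<double>(params["drag_P"]);
  S.gA  = as<double>(params["drag_A"]);
  S.mass = as<double>(params["mass"]);
  double wc = S.sigma_ex * std::pow(2.0, 1.0 / 6.0);
  S.wca_cut2 = wc * wc;
  S.build_dh_table();
  return S;
}

// ---------------------------------------------------------------- forces ----
struct EnergyTerms { double fene, wca, dh, bend, dih; int bad_bond = -1; };

// dihedral angle of quadruple (i,j,k,l); standard atan2 convention
static inline double dihedral_angle(const V3 &ri, const V3 &rj, const V3 &rk, const V3 &rl) {
  V3 b1 = vsub(rj, ri), b2 = vsub(rk, rj), b3 = vsub(rl, rk);
  V3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
  double nb2 = vnorm(b2);
  return std::atan2(vdot(vcross(n1, n2), b2) / nb2, vdot(n1, n2));
}

static inline double wrap_pi(double a) {
  // (-pi, pi]; avoids fmod for portability across libm builds
  a -= TWOPI * std::floor((a + M_PI) / TWOPI);
  if (a > M_PI) a -= TWOPI;
  return a;
}

// pair (Verlet) list over M beads
struct PairList {
  std::vector<int> pi, pj;
  std::vector<V3> ref;
  double skin = 0.5, cut = 0.0;
  bool fresh = false;
  void build(const Sys &S, const std::vector<V3> &x) {
    pi.clear(); pj.clear();
    double c = cut + skin, c2 = c * c;
    for (int i = 0; i < S.nm; i++)
      for (int j = i + 1; j < S.nm; j++) {
        V3 d = vsub(x[i], x[j]);
        if (vdot(d, d) < c2 && !S.excluded(i, j)) { pi.push_back(i); pj.push_back(j); }
      }
    ref.assign(x.begin(), x.begin() + S.nm);
    fresh = true;
  }
  bool needs_rebuild(const Sys &S, const std::vector<V3> &x) const {
    if (ref.empty()) return true;
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < S.nm; i++) {
      V3 d = vsub(x[i], ref[i]);
      if (vdot(d, d) > lim) return true;
    }
    return false;
  }
};

static bool compute_forces(Sys &S, const std::vector<V3> &x, std::vector<V3> &F,
                           EnergyTerms &E, PairList &pl, bool spread_virtual = false) {
  for (int i = 0; i < S.N; i++) F[i] = {0, 0, 0};
  E = EnergyTerms{0, 0, 0, 0, 0, -1};

  // FENE bonds. Beyond |u| = 0.98 the diverging wall is continued linearly:
  // equilibrium occupancy out there is ~e^-12, but a finite continuation
  // keeps a discrete step from tunnelling through the (numerically thin)
  // divergence. |u| >= 1.2 still aborts as a genuine integration failure.
  const double ucap = 0.98;
  for (int k = 0; k < S.nb; k++) {
    int a = S.bond_a[k], b = S.bond_b[k];
    V3 d = vsub(x[a], x[b]);
    double r = vnorm(d);
    double ext = r - S.fr0;
    double u = ext / S.fR0;
    if (std::fabs(u) >= 1.2) { E.bad_bond = k; return false; }
    double fmag;
    if (std::fabs(u) <= ucap) {
      E.fene += -0.5 * S.fK * S.fR0 * S.fR0 * std::log(1.0 - u * u);
      fmag = -S.fK * ext / (1.0 - u * u); // -dU/dr
    } else {
      double sgn = u > 0 ? 1.0 : -1.0;
      double e0 = -0.5 * S.fK * S.fR0 * S.fR0 * std::log(1.0 - ucap * ucap);
      double f0 = S.fK * S.fR0 * ucap / (1.0 - ucap * ucap); // |dU/dr| at cap
      E.fene += e0 + f0 * (std::fabs(ext) - ucap * S.fR0);
      fmag = -sgn * f0;
    }
    V3 f = vscale(d, fmag / r);
    F[a] = vadd(F[a], f); F[b] = vsub(F[b], f);
  }

  // bending
  for (int a = 0; a < S.na; a++) {
    int i = S.ang_i[a], j = S.ang_j[a], k = S.ang_k[a];
    V3 u = vsub(x[j], x[i]), v = vsub(x[k], x[j]);
    double nu = vnorm(u), nv = vnorm(v);
    double ct = vdot(u, v) / (nu * nv);
    if (ct > 1) ct = 1;
    if (ct < -1) ct = -1;
    double K = S.ang_K[a];
    E.bend += K * (1.0 - ct);
    // dcos/du and dcos/dv
    V3 dcdu = vsub(vscale(v, 1.0 / (nu * nv)), vscale(u, ct / (nu * nu)));
    V3 dcdv = vsub(vscale(u, 1.0 / (nu * nv)), vscale(v, ct / (nv * nv)));
    // F = +K * dcos/dx
    V3 Fi = vscale(dcdu, -K);           // x_i enters u with -1
    V3 Fk = vscale(dcdv,  K);
    F[i] = vadd(F[i], Fi);
    F[k] = vadd(F[k], Fk);
    F[j] = vsub(F[j], vadd(Fi, Fk));
  }

  // dihedrals (torsional lock / swivel)
  for (int j = 0; j < S.nj; j++) {
    if (!S.jun_enabled[j]) continue;
    int k1 = S.jun_b1[j], k2 = S.jun_b2[j];
    int Pi = S.nm + S.nb + k1, Aj = S.nm + k1, Ak = S.nm + k2, Pl = S.nm + S.nb + k2;
    V3 b1 = vsub(x[Aj], x[Pi]), b2 = vsub(x[Ak], x[Aj]), b3 = vsub(x[Pl], x[Ak]);
    V3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
    double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
    double nb2 = vnorm(b2);
    if (n1sq < 1e-14 || n2sq < 1e-14 || nb2 < 1e-10) continue; // degenerate frame
    double phi = std::atan2(vdot(vcross(n1, n2), b2) / nb2, vdot(n1, n2));
    double dphi = wrap_pi(phi - S.jun_phase[j]);
    E.dih += S.Kd * (1.0 - std::cos(dphi));
    double dV = S.Kd * std::sin(dphi); // dV/dphi
    V3 Fi = vscale(n1,  dV * nb2 / n1sq);
    V3 Fl = vscale(n2, -dV * nb2 / n2sq);
    double s12 = vdot(b1, b2) / (nb2 * nb2), s32 = vdot(b3, b2) / (nb2 * nb2);
    V3 t = vsub(vscale(Fl, s32), vscale(Fi, s12));
    V3 Fj = vadd(vscale(Fi, -1.0), t);
    V3 Fk = vsub(vscale(Fl, -1.0), t);
    F[Pi] = vadd(F[Pi], Fi); F[Aj] = vadd(F[Aj], Fj);
    F[Ak] = vadd(F[Ak], Fk); F[Pl] = vadd(F[Pl], Fl);
  }

  // nonbonded among M beads
  if (pl.needs_rebuild(S, x)) pl.build(S, x);
  double dh_cut2 = S.dh_cut * S.dh_cut;
  size_t np = pl.pi.size();
  for (size_t q = 0; q < np; q++) {
    int i = pl.pi[q], j = pl.pj[q];
    V3 d = vsub(x[i], x[j]);
    double r2 = vdot(d, d);
    bool cross_gap = (S.gap[i] != S.gap[j]);
    if (r2 < S.wca_cut2 && !(S.topoiii && cross_gap)) {
      double s2 = S.sigma_ex * S.sigma_ex / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      E.wca += 4.0 * (s12 - s6 + 0.25);
      double fr = 4.0 * (12.0 * s12 - 6.0 * s6) / r2; // -(dU/dr)/r
      V3 f = vscale(d, fr);
      F[i] = vadd(F[i], f); F[j] = vsub(F[j], f);
    }
    double qq = S.charge[i] * S.charge[j];
    if (qq != 0.0 && r2 < dh_cut2 && !(S.topoiii && S.topoiii_dh && cross_gap)) {
      double r = std::sqrt(r2);
      double U, dU;
      S.dh_eval(r, U, dU);
      E.dh += qq * U;
      V3 f = vscale(d, -qq * dU / r);
      F[i] = vadd(F[i], f); F[j] = vsub(F[j], f);
    }
  }
  if (spread_virtual) {
    // A beads are virtual sites: forces on them act on the bond midpoint and
    // are carried half-half by the flanking M beads
    for (int k = 0; k < S.nb; k++) {
      int Ai = S.nm + k;
      V3 half = vscale(F[Ai], 0.5);
      F[S.bond_a[k]] = vadd(F[S.bond_a[k]], half);
      F[S.bond_b[k]] = vadd(F[S.bond_b[k]], half);
      F[Ai] = {0, 0, 0};
    }
  }
  return true;
}

// ------------------------------------------------------------ constraints ----
// The axial beads A are massless virtual sites pinned exactly to the bond
// midpoints (their drag and any forces on them are spread onto the flanking
// M beads). The remaining holonomic constraints, per bond k:
//   |P_k - A_k| = 1  and  (P_k - A_k) . (M_b - M_a) = 0,
// are enforced by an iterative symmetric (mass-weighted Lagrange) projection
// over P, M_a and M_b; the frame azimuth is untouched by the projection.

static inline void set_virtual_sites(const Sys &S, std::vector<V3> &x) {
  for (int k = 0; k < S.nb; k++)
    x[S.nm + k] = vscale(vadd(x[S.bond_a[k]], x[S.bond_b[k]]), 0.5);
}
static inline void set_virtual_velocities(const Sys &S, std::vector<V3> &v) {
  for (int k = 0; k < S.nb; k++)
    v[S.nm + k] = vscale(vadd(v[S.bond_a[k]], v[S.bond_b[k]]), 0.5);
}

static int shake_positions(const Sys &S, std::vector<V3> &x, int maxit = 30, double tol = 1e-4) {
  set_virtual_sites(S, x);
  const double sor = 1.0;
  for (int it = 0; it < maxit; it++) {
    double worst = 0.0;
    for (int k = 0; k < S.nb; k++) {
      int a = S.bond_a[k], b = S.bond_b[k], Ai = S.nm + k, Pi = S.nm + S.nb + k;
      // unit-length |P - A|: gradients P: 2d, Ma: -d, Mb: -d (A = midpoint)
      V3 d = vsub(x[Pi], x[Ai]);
      double d2 = vdot(d, d);
      if (d2 < 1e-20) stop("degenerate periaxial frame at bond %d", k + 1);
      double C = d2 - 1.0;
      double lam = -sor * C / (6.0 * d2);
      if (std::fabs(C) > worst) worst = std::fabs(C);
      x[Pi] = vadd(x[Pi], vscale(d, 2.0 * lam));
      x[a] = vsub(x[a], vscale(d, lam));
      x[b] = vsub(x[b], vscale(d, lam));
      x[Ai] = vscale(vadd(x[a], x[b]), 0.5);
      // perpendicularity (P - A) . (Mb - Ma)
      d = vsub(x[Pi], x[Ai]);
      V3 m = vsub(x[b], x[a]);
      double C2 = vdot(d, m);
      if (std::fabs(C2) > worst) worst = std::fabs(C2);
      double m2 = vdot(m, m);
      double lam2 = -sor * C2 / (1.5 * m2 + 2.0 * vdot(d, d));
      V3 gMa = vsub(vscale(m, -0.5), d);  // dC/dMa
      V3 gMb = vadd(vscale(m, -0.5), d);  // dC/dMb
      // dC/dMb = -m/2 + d ; dC/dMa = -m/2 - d
      x[Pi] = vadd(x[Pi], vscale(m, lam2));
      x[a] = vadd(x[a], vscale(gMa, lam2));
      x[b] = vadd(x[b], vscale(gMb, lam2));
      x[Ai] = vscale(vadd(x[a], x[b]), 0.5);
    }
    if (worst < tol) return it + 1;
    if (it == maxit - 1 && worst > 50 * tol && maxit < 400)
      maxit = 400; // slow-convergence fallback: keep sweeping
  }
  return 999;
}

// velocity projection: time derivatives of the two constraints vanish
static int rattle_velocities(const Sys &S, const std::vector<V3> &x, std::vector<V3> &v,
                              int maxit = 30, double tol = 1e-4) {
  set_virtual_velocities(S, v);
  const double sor = 1.0;
  for (int it = 0; it < maxit; it++) {
    double worst = 0.0;
    for (int k = 0; k < S.nb; k++) {
      int a = S.bond_a[k], b = S.bond_b[k], Ai = S.nm + k, Pi = S.nm + S.nb + k;
      V3 d = vsub(x[Pi], x[Ai]);
      V3 m = vsub(x[b], x[a]);
      // d/dt |P-A|^2 = 2 d.(vP - vA)
      V3 dv = vsub(v[Pi], v[Ai]);
      double C = vdot(d, dv);
      if (std::fabs(C) > worst) worst = std::fabs(C);
      double lam = -sor * C / (1.5 * vdot(d, d));
      v[Pi] = vadd(v[Pi], vscale(d, lam));
      v[a] = vsub(v[a], vscale(d, 0.5 * lam));
      v[b] = vsub(v[b], vscale(d, 0.5 * lam));
      v[Ai] = vscale(vadd(v[a], v[b]), 0.5);
      // d/dt [(P-A).m] = (vP - vA).m + (P-A).(vb - va)
      dv = vsub(v[Pi], v[Ai]);
      double C2 = vdot(dv, m) + vdot(d, vsub(v[b], v[a]));
      if (std::fabs(C2) > worst) worst = std::fabs(C2);
      double lam2 = -sor * C2 / (1.5 * vdot(m, m) + 2.0 * vdot(d, d));
      V3 gMa = vsub(vscale(m, -0.5), d);
      V3 gMb = vadd(vscale(m, -0.5), d);
      v[Pi] = vadd(v[Pi], vscale(m, lam2));
      v[a] = vadd(v[a], vscale(gMa, lam2));
      v[b] = vadd(v[b], vscale(gMb, lam2));
      v[Ai] = vscale(vadd(v[a], v[b]), 0.5);
    }
    if (worst < tol) return it + 1;
    if (it == maxit - 1 && worst > 50 * tol && maxit < 400)
      maxit = 400;
  }
  return 999;
}

// -------------------------------------------------------- topology measures ----
// Gauss integral contribution of segment pair (p1->p2, p3->p4), Klenin-Langowski
static inline double gauss_pair(const V3 &p1, const V3 &p2, const V3 &p3, const V3 &p4) {
  V3 r12 = vsub(p2, p1), r34 = vsub(p4, p3);
  V3 r13 = vsub(p3, p1), r14 = vsub(p4, p1), r23 = vsub(p3, p2), r24 = vsub(p4, p2);
  V3 n1 = vcross(r13, r14), n2 = vcross(r14, r24), n3 = vcross(r24, r23), n4 = vcross(r23, r13);
  double a1 = vnorm(n1), a2 = vnorm(n2), a3 = vnorm(n3), a4 = vnorm(n4);
  if (a1 < 1e-12 || a2 < 1e-12 || a3 < 1e-12 || a4 < 1e-12) return 0.0;
  n1 = vscale(n1, 1/a1); n2 = vscale(n2, 1/a2); n3 = vscale(n3, 1/a3); n4 = vscale(n4, 1/a4);
  auto casin = [](double t){ if (t > 1) t = 1; if (t < -1) t = -1; return std::asin(t); };
  double om = casin(vdot(n1, n2)) + casin(vdot(n2, n3)) + casin(vdot(n3, n4)) + casin(vdot(n4, n1));
  double sg = vdot(vcross(r34, r12), r13);
  return (sg >= 0 ? om : -om) / (4.0 * M_PI);
}

static std::vector<V3> mat_to_v3(const NumericMatrix &m) {
  std::vector<V3> x(m.nrow());
  for (int i = 0; i < m.nrow(); i++) x[i] = {m(i,0), m(i,1), m(i,2)};
  return x;
}

// writhe of a polygon (closed: wraps around; open: plain double sum)
static double writhe_poly(const std::vector<V3> &x, bool closed) {
  int n = (int)x.size();
  int ns = closed ? n : n - 1;
  double w = 0.0;
  for (int i = 0; i < ns; i++) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < ns; j++) {
      if (closed && i == 0 && j == ns - 1) continue; // adjacent through closure
      int j2 = (j + 1) % n;
      w += gauss_pair(x[i], x[i2], x[j], x[j2]);
    }
  }
  return 2.0 * w;
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix poly, bool closed) {
  std::vector<V3> x = mat_to_v3(poly);
  int n = (int)x.size();
  int ns = closed ? n : n - 1;
  // guard against touching segments
  for (int i = 0; i < ns; i++) {
    int i2 = (i + 1) % n;
    V3 d = vsub(x[i2], x[i]);
    if (vnorm(d) < 1e-9) stop("degenerate (zero length) segment %d", i + 1);
  }
  return writhe_poly(x, closed);
}

// [[Rcpp::export]]
double cpp_linking(NumericMatrix polyA, NumericMatrix polyB) {
  std::vector<V3> a = mat_to_v3(polyA), b = mat_to_v3(polyB);
  int na = (int)a.size(), nbp = (int)b.size();
  double L = 0.0;
  for (int i = 0; i < na; i++) {
    int i2 = (i + 1) % na;
    for (int j = 0; j < nbp; j++) {
      int j2 = (j + 1) % nbp;
      L += gauss_pair(a[i], a[i2], b[j], b[j2]);
    }
  }
  return L;
}

// twist of the periaxial ribbon of one chain: sum over junctions of the
// rotation of the P offset relative to parallel transport across the vertex.
// mode 0: geometric; mode 1: strain (phase-subtracted)
static double chain_twist(const Sys &S, const std::vector<V3> &x, const Chain &C, int mode) {
  double tw = 0.0;
  for (int jj = 0; jj < C.njun; jj++) {
    int j = C.jun0 + jj;
    int k1 = S.jun_b1[j], k2 = S.jun_b2[j];
    V3 t1 = vsub(x[S.bond_b[k1]], x[S.bond_a[k1]]);
    V3 t2 = vsub(x[S.bond_b[k2]], x[S.bond_a[k2]]);
    double n1 = vnorm(t1), n2 = vnorm(t2);
    t1 = vscale(t1, 1/n1); t2 = vscale(t2, 1/n2);
    V3 u1 = vsub(x[S.nm + S.nb + k1], x[S.nm + k1]);
    V3 u2 = vsub(x[S.nm + S.nb + k2], x[S.nm + k2]);
    // parallel-transport u1 from frame t1 to t2 (Rodrigues about t1 x t2)
    V3 ax = vcross(t1, t2);
    double sa = vnorm(ax), ca = vdot(t1, t2);
    V3 u1t = u1;
    if (sa > 1e-12) {
      V3 k = vscale(ax, 1.0 / sa);
      u1t = vadd(vadd(vscale(u1, ca), vscale(vcross(k, u1), sa)),
                 vscale(k, vdot(k, u1) * (1.0 - ca)));
    }
    double ang = std::atan2(vdot(vcross(u1t, u2), t2), vdot(u1t, u2));
    if (mode == 1) ang = wrap_pi(ang - S.jun_phase[j]);
    tw += ang;
  }
  return tw / TWOPI;
}

// [[Rcpp::export]]
NumericVector cpp_twist(NumericMatrix pos, List topo, List params, int mode) {
  Sys S = parse_sys(topo, params);
  std::vector<V3> x = mat_to_v3(pos);
  NumericVector out(S.chains.size());
  for (size_t c = 0; c < S.chains.size(); c++) out[c] = chain_twist(S, x, S.chains[c], mode);
  return out;
}

// ------------------------------------------------------------------- KMT ----
// does segment (a,b) intersect triangle (t0,t1,t2)? conservative epsilons
static bool seg_hits_tri(const V3 &a, const V3 &b, const V3 &t0, const V3 &t1, const V3 &t2) {
  const double eps = 1e-9;
  V3 e1 = vsub(t1, t0), e2 = vsub(t2, t0), dir = vsub(b, a);
  V3 p = vcross(dir, e2);
  double det = vdot(e1, p);
  if (std::fabs(det) < eps) {
    // near-coplanar: be conservative (treat as blocking) when the bounding
    // boxes come close -- removing the vertex could let the segment pass
    double lo, hi, tl, th;
    const double pad = 1e-7;
    lo = std::min(a.x, b.x) - pad; hi = std::max(a.x, b.x) + pad;
    tl = std::min(t0.x, std::min(t1.x, t2.x)); th = std::max(t0.x, std::max(t1.x, t2.x));
    if (hi < tl || lo > th) return false;
    lo = std::min(a.y, b.y) - pad; hi = std::max(a.y, b.y) + pad;
    tl = std::min(t0.y, std::min(t1.y, t2.y)); th = std::max(t0.y, std::max(t1.y, t2.y));
    if (hi < tl || lo > th) return false;
    lo = std::min(a.z, b.z) - pad; hi = std::max(a.z, b.z) + pad;
    tl = std::min(t0.z, std::min(t1.z, t2.z)); th = std::max(t0.z, std::max(t1.z, t2.z));
    if (hi < tl || lo > th) return false;
    return true;
  }
  double inv = 1.0 / det;
  V3 tv = vsub(a, t0);
  double u = vdot(tv, p) * inv;
  if (u < -eps || u > 1 + eps) return false;
  V3 q = vcross(tv, e1);
  double v = vdot(dir, q) * inv;
  if (v < -eps || u + v > 1 + eps) return false;
  double t = vdot(e2, q) * inv;
  if (t < -eps || t > 1 + eps) return false;
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix poly) {
  std::vector<V3> x = mat_to_v3(poly);
  std::vector<int> idx(x.size());
  for (size_t i = 0; i < x.size(); i++) idx[i] = (int)i;
  bool changed = true;
  while (changed && idx.size() > 3) {
    changed = false;
    for (size_t ii = 0; ii < idx.size() && idx.size() > 3; ii++) {
      size_t n = idx.size();
      size_t ip = (ii + n - 1) % n, in_ = (ii + 1) % n;
      V3 A = x[idx[ip]], B = x[idx[ii]], C = x[idx[in_]];
      bool blocked = false;
      for (size_t e = 0; e < n && !blocked; e++) {
        size_t e2 = (e + 1) % n;
        if (e == ip || e == ii || e2 == ip || e2 == ii || e == in_ ) continue;
        if (e2 == in_ && e == ii) continue;
        // skip edges sharing a vertex with the triangle
        if (idx[e] == idx[ip] || idx[e] == idx[ii] || idx[e] == idx[in_]) continue;
        if (idx[e2] == idx[ip] || idx[e2] == idx[ii] || idx[e2] == idx[in_]) continue;
        if (seg_hits_tri(x[idx[e]], x[idx[e2]], A, B, C)) blocked = true;
      }
      if (!blocked) {
        idx.erase(idx.begin() + ii);
        changed = true;
        if (ii > 0) ii--;
      }
    }
  }
  NumericMatrix out((int)idx.size(), 3);
  for (size_t i = 0; i < idx.size(); i++) {
    out(i,0) = x[idx[i]].x; out(i,1) = x[idx[i]].y; out(i,2) = x[idx[i]].z;
  }
  return out;
}

// ---------------------------------------------------------- knot diagram ----
// Project closed polygon onto xy (after caller-applied rotation) and list
// crossings. Returns list(ok, crossings) where crossings has columns:
// edge1, t1, edge2, t2, over1 (1 if strand 1 passes over).
// [[Rcpp::export]]
List cpp_diagram(NumericMatrix poly) {
  int n = poly.nrow();
  std::vector<V3> x = mat_to_v3(poly);
  std::vector<double> e1c, t1c, e2c, t2c, ov;
  const double eps = 1e-9, endeps = 1e-7;
  for (int i = 0; i < n; i++) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; j++) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue; // adjacent edges share a vertex
      double x1 = x[i].x, y1 = x[i].y, x2 = x[i2].x, y2 = x[i2].y;
      double x3 = x[j].x, y3 = x[j].y, x4 = x[j2].x, y4 = x[j2].y;
      double den = (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3);
      double num_t = (x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3);
      double num_s = (x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1);
      if (std::fabs(den) < eps) {
        // parallel in projection; if they also overlap, projection is degenerate
        continue;
      }
      double t = num_t / den, s = num_s / den;
      if (t <= -endeps || t >= 1 + endeps || s <= -endeps || s >= 1 + endeps) continue;
      if (t < endeps || t > 1 - endeps || s < endeps || s > 1 - endeps)
        return List::create(_["ok"] = false); // crossing at a vertex: retry projection
      double z1 = x[i].z + t * (x[i2].z - x[i].z);
      double z2 = x[j].z + s * (x[j2].z - x[j].z);
      if (std::fabs(z1 - z2) < 1e-9) return List::create(_["ok"] = false);
      e1c.push_back(i); t1c.push_back(t);
      e2c.push_back(j); t2c.push_back(s);
      ov.push_back(z1 > z2 ? 1.0 : 0.0);
    }
  }
  int m = (int)e1c.size();
  NumericMatrix cr(m, 5);
  for (int q = 0; q < m; q++) {
    cr(q,0) = e1c[q]; cr(q,1) = t1c[q]; cr(q,2) = e2c[q]; cr(q,3) = t2c[q]; cr(q,4) = ov[q];
  }
  return List::create(_["ok"] = true, _["crossings"] = cr);
}

// ------------------------------------------------------------- energies ----
// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, List topo, List params) {
  Sys S = parse_sys(topo, params);
  if (pos.nrow() != S.N) stop("position matrix has %d rows; topology requires %d", pos.nrow(), S.N);
  std::vector<V3> x = mat_to_v3(pos);
  std::vector<V3> F(S.N);
  EnergyTerms E;
  PairList pl; pl.cut = std::max(S.dh_cut, std::sqrt(S.wca_cut2));
  if (!compute_forces(S, x, F, E, pl))
    stop("FENE bond %d stretched beyond maximum extension", E.bad_bond + 1);
  return List::create(_["fene"] = E.fene, _["wca"] = E.wca, _["dh"] = E.dh,
                      _["bend"] = E.bend, _["dihedral"] = E.dih,
                      _["total"] = E.fene + E.wca + E.dh + E.bend + E.dih);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, List topo, List params) {
  Sys S = parse_sys(topo, params);
  if (pos.nrow() != S.N) stop("position matrix has %d rows; topology requires %d", pos.nrow(), S.N);
  std::vector<V3> x = mat_to_v3(pos);
  std::vector<V3> F(S.N);
  EnergyTerms E;
  PairList pl; pl.cut = std::max(S.dh_cut, std::sqrt(S.wca_cut2));
  if (!compute_forces(S, x, F, E, pl))
    stop("FENE bond %d stretched beyond maximum extension", E.bad_bond + 1);
  NumericMatrix out(S.N, 3);
  for (int i = 0; i < S.N; i++) { out(i,0)=F[i].x; out(i,1)=F[i].y; out(i,2)=F[i].z; }
  return out;
}

// [[Rcpp::export]]
List cpp_project_constraints(NumericMatrix pos, NumericMatrix vel, List topo, List params) {
  Sys S = parse_sys(topo, params);
  std::vector<V3> x = mat_to_v3(pos), v = mat_to_v3(vel);
  shake_positions(S, x, 500, 1e-12);
  rattle_velocities(S, x, v, 500, 1e-13);
  NumericMatrix xo(S.N, 3), vo(S.N, 3);
  for (int i = 0; i < S.N; i++) {
    xo(i,0)=x[i].x; xo(i,1)=x[i].y; xo(i,2)=x[i].z;
    vo(i,0)=v[i].x; vo(i,1)=v[i].y; vo(i,2)=v[i].z;
  }
  return List::create(_["positions"] = xo, _["velocities"] = vo);
}

// [[Rcpp::export]]
IntegerVector cpp_projection_diag(NumericMatrix pos, NumericMatrix vel, List topo, List params) {
  Sys S = parse_sys(topo, params);
  std::vector<V3> x = mat_to_v3(pos), v = mat_to_v3(vel);
  int i1 = shake_positions(S, x);
  int i2 = rattle_velocities(S, x, v);
  return IntegerVector::create(i1, i2);
}

// ---------------------------------------------------------------- run ----
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, List topo, List params, List settings) {
  Sys S = parse_sys(topo, params);
  if (pos0.nrow() != S.N) stop("position matrix has %d rows; topology requires %d", pos0.nrow(), S.N);
  std::vector<V3> x = mat_to_v3(pos0), v = mat_to_v3(vel0);

  double dt = as<double>(settings["timestep"]);
  double n_steps_d = as<double>(settings["n_steps"]);
  long long n_steps = (long long)(n_steps_d + 0.5);
  int obs_every = as<int>(settings["obs_every"]);
  int snap_every = as<int>(settings["snap_every"]);
  bool thermostat = as<bool>(settings["thermostat"]);
  double kT_set = settings.containsElementNamed("kT") ? as<double>(settings["kT"]) : S.kT;
  // optional constant external forces on selected beads
  std::vector<int> ext_idx;
  std::vector<V3> ext_f;
  if (settings.containsElementNamed("ext_idx")) {
    IntegerVector ei = settings["ext_idx"];
    NumericMatrix ef = settings["ext_force"];
    for (int q = 0; q < ei.size(); q++) {
      ext_idx.push_back(ei[q]);
      ext_f.push_back({ef(q,0), ef(q,1), ef(q,2)});
    }
  }
  int track_bond = as<int>(settings["track_bond"]); // 0-based, -1 = off
  uint64_t seed = (uint64_t)as<double>(settings["seed"]);
  double kT = thermostat ? kT_set : 0.0;

  RNG rng; rng.seed(seed);

  // per-particle drag and noise amplitude; A beads are virtual sites (their
  // drag gA acts on the midpoint velocity and is spread onto the M pair)
  std::vector<double> gam(S.N, 0.0), namp(S.N, 0.0);
  for (int i = 0; i < S.N; i++) {
    double g = (i < S.nm) ? S.gM : (i < S.nm + S.nb ? 0.0 : S.gP);
    if (!thermostat) g = 0.0;
    gam[i] = g;
    namp[i] = (g > 0 && dt > 0) ? std::sqrt(2.0 * g * kT / dt) : 0.0;
  }
  double gA = thermostat ? S.gA : 0.0;
  double nampA = (gA > 0 && dt > 0) ? std::sqrt(2.0 * gA * kT / dt) : 0.0;
  std::vector<V3> xiA(S.nb, V3{0, 0, 0});

  PairList pl; pl.cut = std::max(S.dh_cut, std::sqrt(S.wca_cut2));
  std::vector<V3> Fp(S.N), xi(S.N, V3{0,0,0}), xpred(S.N);
  EnergyTerms E;
  shake_positions(S, x);
  rattle_velocities(S, x, v);
  auto add_ext = [&]() {
    for (size_t q = 0; q < ext_idx.size(); q++)
      Fp[ext_idx[q]] = vadd(Fp[ext_idx[q]], ext_f[q]);
  };
  if (!compute_forces(S, x, Fp, E, pl, true))
    stop("FENE bond %d overstretched in the initial state", E.bad_bond + 1);
  add_ext();

  // azimuth tracking state
  bool track = track_bond >= 0 && track_bond < S.nb;
  V3 tr_t{0,0,0}, tr_u{0,0,0};
  double tr_cum = 0.0;
  auto bond_frame = [&](int k, V3 &t, V3 &u) {
    t = vsub(x[S.bond_b[k]], x[S.bond_a[k]]);
    t = vscale(t, 1.0 / vnorm(t));
    u = vsub(x[S.nm + S.nb + k], x[S.nm + k]);
  };
  if (track) bond_frame(track_bond, tr_t, tr_u);

  int n_chains = (int)S.chains.size();
  // observable buffers
  std::vector<double> ob_step, ob_fene, ob_wca, ob_dh, ob_bend, ob_dih, ob_kin,
      ob_rot, ob_az;
  std::vector<std::vector<double> > ob_tw(n_chains), ob_tws(n_chains), ob_wr(n_chains);
  std::vector<double> ob_lk12;
  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_steps;

  long long bad_step = -1; int bad_bead = -1, bad_bond = -1;

  auto log_obs = [&](long long step) {
    ob_step.push_back((double)step);
    ob_fene.push_back(E.fene); ob_wca.push_back(E.wca); ob_dh.push_back(E.dh);
    ob_bend.push_back(E.bend); ob_dih.push_back(E.dih);
    double kin = 0; // M and P beads only; A beads are massless virtual sites
    for (int i = 0; i < S.nm; i++) kin += 0.5 * S.mass * vdot(v[i], v[i]);
    for (int i = S.nm + S.nb; i < S.N; i++) kin += 0.5 * S.mass * vdot(v[i], v[i]);
    ob_kin.push_back(kin);
    double rot = 0;
    for (int j = 0; j < S.nj; j++)
      if (S.jun_active[j]) rot += std::fabs(S.jun_phase[j]) / TWOPI;
    ob_rot.push_back(rot);
    ob_az.push_back(tr_cum);
    for (int c = 0; c < n_chains; c++) {
      const Chain &C = S.chains[c];
      ob_tw[c].push_back(chain_twist(S, x, C, 0));
      ob_tws[c].push_back(chain_twist(S, x, C, 1));
      std::vector<V3> sub(x.begin() + C.first, x.begin() + C.first + C.n_units);
      ob_wr[c].push_back(C.circular ? writhe_poly(sub, true) : writhe_poly(sub, false));
    }
    if (n_chains == 2) {
      const Chain &C1 = S.chains[0], &C2 = S.chains[1];
      double L = 0;
      for (int i = 0; i < C1.n_units; i++) {
        int i2 = (i + 1) % C1.n_units;
        for (int j = 0; j < C2.n_units; j++) {
          int j2 = (j + 1) % C2.n_units;
          L += gauss_pair(x[C1.first + i], x[C1.first + i2], x[C2.first + j], x[C2.first + j2]);
        }
      }
      ob_lk12.push_back(L);
    }
  };
  auto take_snap = [&](long long step) {
    NumericMatrix m(S.N, 3);
    for (int i = 0; i < S.N; i++) { m(i,0)=x[i].x; m(i,1)=x[i].y; m(i,2)=x[i].z; }
    snaps.push_back(m);
    snap_steps.push_back((double)step);
  };

  log_obs(0);
  take_snap(0);

  long long step = 0;
  for (step = 1; step <= n_steps; step++) {
    // advance active swivel phases (continuous ramp)
    for (int j = 0; j < S.nj; j++)
      if (S.jun_active[j]) S.jun_phase[j] += TWOPI * S.jun_rate[j] * S.jun_sign[j] * dt;
    // fresh noise for this step
    if (thermostat) {
      for (int i = 0; i < S.nm; i++)
        xi[i] = {namp[i] * rng.norm(), namp[i] * rng.norm(), namp[i] * rng.norm()};
      for (int i = S.nm + S.nb; i < S.N; i++)
        xi[i] = {namp[i] * rng.norm(), namp[i] * rng.norm(), namp[i] * rng.norm()};
      for (int k = 0; k < S.nb; k++)
        xiA[k] = {nampA * rng.norm(), nampA * rng.norm(), nampA * rng.norm()};
    }
    double hdt = 0.5 * dt / S.mass;
    // half kick (previous potential force + friction + noise); the A-site
    // drag/noise acts on the midpoint velocity and is spread half-half
    auto kick = [&]() {
      for (int i = 0; i < S.nm; i++) {
        V3 f = vadd(vsub(Fp[i], vscale(v[i], gam[i])), xi[i]);
        v[i] = vadd(v[i], vscale(f, hdt));
      }
      for (int i = S.nm + S.nb; i < S.N; i++) {
        V3 f = vadd(vsub(Fp[i], vscale(v[i], gam[i])), xi[i]);
        v[i] = vadd(v[i], vscale(f, hdt));
      }
      if (gA > 0)
        for (int k = 0; k < S.nb; k++) {
          int a = S.bond_a[k], b = S.bond_b[k];
          V3 vA = vscale(vadd(v[a], v[b]), 0.5);
          V3 fA = vadd(vscale(vA, -gA), xiA[k]);
          V3 half = vscale(fA, 0.5 * hdt);
          v[a] = vadd(v[a], half);
          v[b] = vadd(v[b], half);
        }
    };
    kick();
    // drift + constraint projection (the projection displacement feeds back
    // into the velocities, as in standard SHAKE)
    for (int i = 0; i < S.nm; i++) x[i] = vadd(x[i], vscale(v[i], dt));
    for (int i = S.nm + S.nb; i < S.N; i++) x[i] = vadd(x[i], vscale(v[i], dt));
    xpred = x;
    shake_positions(S, x);
    for (int i = 0; i < S.nm; i++)
      v[i] = vadd(v[i], vscale(vsub(x[i], xpred[i]), 1.0 / dt));
    for (int i = S.nm + S.nb; i < S.N; i++)
      v[i] = vadd(v[i], vscale(vsub(x[i], xpred[i]), 1.0 / dt));
    // new forces
    if (!compute_forces(S, x, Fp, E, pl, true)) { bad_step = step; bad_bond = E.bad_bond; break; }
    add_ext();
    // closing half kick
    kick();
    rattle_velocities(S, x, v);
    // non-finite check
    if ((step & 1023) == 0) {
      for (int i = 0; i < S.N; i++)
        if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) || !std::isfinite(x[i].z)) {
          bad_step = step; bad_bead = i; break;
        }
      if (bad_step >= 0) break;
    }
    // azimuth tracking (every step for continuity)
    if (track) {
      V3 t2, u2;
      bond_frame(track_bond, t2, u2);
      V3 ax = vcross(tr_t, t2);
      double sa = vnorm(ax), ca = vdot(tr_t, t2);
      V3 u1t = tr_u;
      if (sa > 1e-12) {
        V3 kv = vscale(ax, 1.0 / sa);
        u1t = vadd(vadd(vscale(tr_u, ca), vscale(vcross(kv, tr_u), sa)),
                   vscale(kv, vdot(kv, tr_u) * (1.0 - ca)));
      }
      tr_cum += std::atan2(vdot(vcross(u1t, u2), t2), vdot(u1t, u2));
      tr_t = t2; tr_u = u2;
    }
    if (obs_every > 0 && step % obs_every == 0) log_obs(step);
    if (snap_every > 0 && step % snap_every == 0) take_snap(step);
    if ((step & 8191) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xo(S.N, 3), vo(S.N, 3);
  for (int i = 0; i < S.N; i++) {
    xo(i,0)=x[i].x; xo(i,1)=x[i].y; xo(i,2)=x[i].z;
    vo(i,0)=v[i].x; vo(i,1)=v[i].y; vo(i,2)=v[i].z;
  }
  List obs = List::create(
    _["step"] = wrap(ob_step), _["E_fene"] = wrap(ob_fene), _["E_wca"] = wrap(ob_wca),
    _["E_dh"] = wrap(ob_dh), _["E_bend"] = wrap(ob_bend), _["E_dih"] = wrap(ob_dih),
    _["E_kin"] = wrap(ob_kin), _["rotations"] = wrap(ob_rot), _["azimuth"] = wrap(ob_az));
  List tw_l(n_chains), tws_l(n_chains), wr_l(n_chains);
  for (int c = 0; c < n_chains; c++) {
    tw_l[c] = wrap(ob_tw[c]); tws_l[c] = wrap(ob_tws[c]); wr_l[c] = wrap(ob_wr[c]);
  }
  return List::create(
    _["positions"] = xo, _["velocities"] = vo,
    _["phases"] = wrap(S.jun_phase),
    _["obs"] = obs, _["tw"] = tw_l, _["tw_strain"] = tws_l, _["wr"] = wr_l,
    _["lk12"] = wrap(ob_lk12),
    _["snapshots"] = wrap(snaps), _["snap_steps"] = wrap(snap_steps),
    _["ok"] = (bad_step < 0),
    _["bad_step"] = (double)bad_step, _["bad_bead"] = bad_bead + 1, _["bad_bond"] = bad_bond + 1,
    _["steps_done"] = (double)std::min(step, n_steps));
}
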