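// Coarse-grained force field + Langevin engine.
//
// Bead-level model: 3SPN-style DNA (P/S/B sites) and C-alpha Go protein.
// All energies in kcal/mol, lengths in Angstrom, mass = 1 per bead,
// reduced time units. Single-threaded and bitwise deterministic for a
// fixed seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG: xoshiro256++ seeded through splitmix64
// ---------------------------------------------------------------------------
struct XRng {
  uint64_t s[4];
  bool have_g;
  double g;
  explicit XRng(uint64_t seed) : have_g(false), g(0.0) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // Box-Muller, cached second deviate
  inline double norm() {
    if (have_g) { have_g = false; return g; }
    double u1 = unif(), u2 = unif();
    if (u1 <= 0.0) u1 = 5e-324;
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    g = r * std::sin(a); have_g = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// fast exp on [-16, 0.5]: node table + 3rd-order Taylor remainder
// absolute relative error < 1e-12, smooth enough for force consistency
// ---------------------------------------------------------------------------
static const int EXP_N = 8192;
static const double EXP_LO = -16.0, EXP_HI = 0.5;
static double EXP_H, EXP_INVH;
static std::vector<double> EXP_T;
static bool exp_init_done = false;

static void exp_init() {
  if (exp_init_done) return;
  EXP_H = (EXP_HI - EXP_LO) / EXP_N;
  EXP_INVH = 1.0 / EXP_H;
  EXP_T.resize(EXP_N + 2);
  for (int i = 0; i <= EXP_N + 1; ++i) EXP_T[i] = std::exp(EXP_LO + i * EXP_H);
  exp_init_done = true;
}

static inline double fast_exp(double x) {
  // NaN-safe: any non-finite or out-of-range argument takes the slow path
  if (!(x >= EXP_LO && x <= EXP_HI)) return std::exp(x);
  double u = (x - EXP_LO) * EXP_INVH;
  int i = (int)u;
  double d = x - (EXP_LO + i * EXP_H);
  return EXP_T[i] * (1.0 + d * (1.0 + d * (0.5 + d * (1.0 / 6.0))));
}

// ---------------------------------------------------------------------------
// system container (unpacked once per call from the R list)
// ---------------------------------------------------------------------------
// energy component slots
enum Comp {
  C_DNA_BOND = 0, C_DNA_ANGLE, C_DNA_DIH, C_STACK, C_PAIRING, C_SOLVENT,
  C_EV, C_ELEC, C_CAGE, C_RESTRAINT, C_PRO_BOND, C_PRO_ANGLE, C_PRO_DIH,
  C_PRO_NATIVE, C_PRO_NONNATIVE, C_SPECIFIC, C_NONSPECIFIC, N_COMP
};

struct Sys {
  int n;
  double box[3];
  std::vector<int> frozen;       // 0/1
  std::vector<double> charge;
  std::vector<double> sigma;     // per-bead excluded-volume radius parameter
  double ev_eps;
  std::vector<int> is_base;      // 0/1
  std::vector<int> mol;          // 0 = DNA, 1 = protein

  // bonded
  std::vector<int> bonds; std::vector<double> bond_r0, bond_k2, bond_k4;
  std::vector<int> bond_comp;
  std::vector<int> angles; std::vector<double> ang_t0, ang_k;
  std::vector<int> ang_comp;
  std::vector<int> dihs; std::vector<double> dih_phi0, dih_k1, dih_k3;
  std::vector<int> dih_comp;

  // fixed pair wells
  std::vector<int> p1210; std::vector<double> p1210_r0, p1210_eps;
  std::vector<int> p1210_comp;
  std::vector<int> p126; std::vector<double> p126_r0, p126_eps, p126_cut;
  std::vector<int> p126_comp;

  // exclusions (sorted keys i*n + j, i < j)
  std::vector<double> excl_ev, excl_elec, excl_solv;

  // electrostatics
  double lambda, kpref, cross_scale, elec_cut;

  // solvent-induced cohesion between base beads
  bool solv_on;
  double solv_eps, solv_r0, solv_alpha, solv_cut;

  // cage
  bool cage_on, cage_shift;
  double cage_R, cage_K, cage_C;
  double axis_a[3], axis_u[3];
  std::vector<int> cage_pairs;   // base-bead pairs defining bp centers

  // restraints: p = bead i (if j == i) or midpoint of i,j; U = k |p - p0|^2
  std::vector<int> res_i, res_j;
  std::vector<double> res_p, res_k;

  std::vector<int> charged_idx;
};

static std::vector<double> sorted_keys(SEXP x) {
  NumericVector v(x);
  std::vector<double> out(v.begin(), v.end());
  std::sort(out.begin(), out.end());
  return out;
}
static inline bool in_keys(const std::vector<double>& keys, double k) {
  return std::binary_search(keys.begin(), keys.end(), k);
}
static inline double pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (double)i * (double)n + (double)j;
}

static void unpack_ints(SEXP m, std::vector<int>& out) {
  IntegerMatrix im(m);
  out.resize(im.nrow() * im.ncol());
  for (int r = 0; r < im.nrow(); ++r)
    for (int c = 0; c < im.ncol(); ++c) out[r * im.ncol() + c] = im(r, c);
}
static void unpack_num(SEXP v, std::vector<double>& out) {
  NumericVector nv(v);
  out.assign(nv.begin(), nv.end());
}
static void unpack_int(SEXP v, std::vector<int>& out) {
  IntegerVector nv(v);
  out.assign(nv.begin(), nv.end());
}

static Sys unpack(const List& sys) {
  exp_init();
  Sys S;
  S.n = as<int>(sys["n"]);
  NumericVector bx = sys["box"];
  for (int d = 0; d < 3; ++d) S.box[d] = bx[d];
  unpack_int(sys["frozen"], S.frozen);
  unpack_num(sys["charge"], S.charge);
  unpack_num(sys["ev_sigma"], S.sigma);
  S.ev_eps = as<double>(sys["ev_eps"]);
  unpack_int(sys["is_base"], S.is_base);
  unpack_int(sys["mol"], S.mol);

  unpack_ints(sys["bonds"], S.bonds);
  unpack_num(sys["bond_r0"], S.bond_r0);
  unpack_num(sys["bond_k2"], S.bond_k2);
  unpack_num(sys["bond_k4"], S.bond_k4);
  unpack_int(sys["bond_comp"], S.bond_comp);

  unpack_ints(sys["angles"], S.angles);
  unpack_num(sys["angle_t0"], S.ang_t0);
  unpack_num(sys["angle_k"], S.ang_k);
  unpack_int(sys["angle_comp"], S.ang_comp);

  unpack_ints(sys["dihedrals"], S.dihs);
  unpack_num(sys["dih_phi0"], S.dih_phi0);
  unpack_num(sys["dih_k1"], S.dih_k1);
  unpack_num(sys["dih_k3"], S.dih_k3);
  unpack_int(sys["dih_comp"], S.dih_comp);

  unpack_ints(sys["pairs1210"], S.p1210);
  unpack_num(sys["p1210_r0"], S.p1210_r0);
  unpack_num(sys["p1210_eps"], S.p1210_eps);
  unpack_int(sys["p1210_comp"], S.p1210_comp);

  unpack_ints(sys["pairs126"], S.p126);
  unpack_num(sys["p126_r0"], S.p126_r0);
  unpack_num(sys["p126_eps"], S.p126_eps);
  unpack_num(sys["p126_cut"], S.p126_cut);
  unpack_int(sys["p126_comp"], S.p126_comp);

  S.excl_ev = sorted_keys(sys["excl_ev"]);
  S.excl_elec = sorted_keys(sys["excl_elec"]);
  S.excl_solv = sorted_keys(sys["excl_solv"]);

  List el = sys["elec"];
  S.lambda = as<double>(el["lambda"]);
  S.kpref = as<double>(el["kpref"]);
  S.cross_scale = as<double>(el["cross_scale"]);
  S.elec_cut = as<double>(el["cutoff"]);

  List sv = sys["solvent"];
  S.solv_on = as<bool>(sv["on"]);
  S.solv_eps = as<double>(sv["eps"]);
  S.solv_r0 = as<double>(sv["r0"]);
  S.solv_alpha = as<double>(sv["alpha"]);
  S.solv_cut = as<double>(sv["cutoff"]);

  List cg = sys["cage"];
  S.cage_on = as<bool>(cg["on"]);
  if (S.cage_on) {
    S.cage_R = as<double>(cg["R"]);
    S.cage_K = as<double>(cg["K"]);
    S.cage_C = as<double>(cg["C"]);
    S.cage_shift = as<bool>(cg["continuity_shift"]);
    NumericVector a = cg["axis_a"], u = cg["axis_u"];
    for (int d = 0; d < 3; ++d) { S.axis_a[d] = a[d]; S.axis_u[d] = u[d]; }
    unpack_ints(cg["pairs"], S.cage_pairs);
  } else {
    S.cage_R = 0; S.cage_K = 0; S.cage_C = 0; S.cage_shift = false;
  }

  List rs = sys["restraints"];
  unpack_int(rs["i"], S.res_i);
  unpack_int(rs["j"], S.res_j);
  unpack_num(rs["p"], S.res_p);   // length 3m, row-major xyz
  unpack_num(rs["k"], S.res_k);

  for (int i = 0; i < S.n; ++i)
    if (S.charge[i] != 0.0) S.charged_idx.push_back(i);
  return S;
}

// ---------------------------------------------------------------------------
// neighbour lists
// ---------------------------------------------------------------------------
struct NList {
  std::vector<int> ev;     // pairs, flattened
  std::vector<int> solv;
  std::vector<int> elec;           // near pairs
  std::vector<double> elec_pref;   // kpref * scale * qi * qj per pair
  std::vector<int> elec_far;       // far pairs (multiple-timestep slot)
  std::vector<double> elec_far_pref;
};

static inline void min_image(double* d, const double* box) {
  for (int k = 0; k < 3; ++k) {
    double u = d[k] / box[k];
    d[k] -= box[k] * (double)(long long)(u >= 0.0 ? u + 0.5 : u - 0.5);
  }
}

static void build_nlist(const Sys& S, const double* x, double skin,
                        bool skip_frozen, NList& L, double mts_r = 0.0) {
  L.ev.clear(); L.solv.clear(); L.elec.clear();
  L.elec_far.clear(); L.elec_far_pref.clear();
  const int n = S.n;
  double sig_max = 0.0;
  for (int i = 0; i < n; ++i) sig_max = std::max(sig_max, S.sigma[i]);
  const double cut_ev = 1.122462048309373 * sig_max + skin;
  const double cut_ev2 = cut_ev * cut_ev;
  const double cut_sv = S.solv_cut + skin;
  const double cut_sv2 = cut_sv * cut_sv;
  const double big2 = std::max(cut_ev2, S.solv_on ? cut_sv2 : 0.0);

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (skip_frozen && S.frozen[i] && S.frozen[j]) continue;
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      min_image(d, S.box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 >= big2) continue;
      double key = pkey(i, j, n);
      if (r2 < cut_ev2 && !in_keys(S.excl_ev, key)) {
        L.ev.push_back(i); L.ev.push_back(j);
      }
      if (S.solv_on && S.is_base[i] && S.is_base[j] && r2 < cut_sv2 &&
          !in_keys(S.excl_solv, key)) {
        L.solv.push_back(i); L.solv.push_back(j);
      }
    }
  }
  const double cut_el = S.elec_cut + skin;
  const double cut_el2 = cut_el * cut_el;
  const int nc = (int)S.charged_idx.size();
  L.elec_pref.clear();
  for (int a = 0; a < nc - 1; ++a) {
    int i = S.charged_idx[a];
    for (int b = a + 1; b < nc; ++b) {
      int j = S.charged_idx[b];
      if (skip_frozen && S.frozen[i] && S.frozen[j]) continue;
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      min_image(d, S.box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < cut_el2 && !in_keys(S.excl_elec, pkey(i, j, n))) {
        double scale = (S.mol[i] != S.mol[j]) ? S.cross_scale : 1.0;
        double pref = S.kpref * scale * S.charge[i] * S.charge[j];
        if (mts_r > 0.0 && r2 >= mts_r * mts_r) {
          L.elec_far.push_back(i); L.elec_far.push_back(j);
          L.elec_far_pref.push_back(pref);
        } else {
          L.elec.push_back(i); L.elec.push_back(j);
          L.elec_pref.push_back(pref);
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// force / energy evaluation
// ---------------------------------------------------------------------------
struct ForceOut {
  std::vector<double> f;          // 3n
  double comp[N_COMP];
  bool cage_violation;            // some d_i >= R - 0.01
  double cage_maxd;
};

static inline void fadd(std::vector<double>& f, int i, const double* v, double s) {
  f[3*i] += s * v[0]; f[3*i+1] += s * v[1]; f[3*i+2] += s * v[2];
}

static void eval_forces(const Sys& S, const double* x, const NList& L,
                        bool skip_frozen, ForceOut& out) {
  const int n = S.n;
  out.f.assign(3 * n, 0.0);
  for (int c = 0; c < N_COMP; ++c) out.comp[c] = 0.0;
  out.cage_violation = false;
  out.cage_maxd = 0.0;
  std::vector<double>& f = out.f;

  // ---- bonds: U = k2 d^2 + k4 d^4, d = r - r0 (no PBC: unwrapped coords)
  const int nb = (int)S.bonds.size() / 2;
  for (int b = 0; b < nb; ++b) {
    int i = S.bonds[2*b], j = S.bonds[2*b+1];
    if (skip_frozen && S.frozen[i] && S.frozen[j]) continue;
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r < 1e-9) stop("coincident bonded beads (bond %d-%d)", i + 1, j + 1);
    double dd = r - S.bond_r0[b];
    out.comp[S.bond_comp[b]] += S.bond_k2[b]*dd*dd + S.bond_k4[b]*dd*dd*dd*dd;
    double dUdr = 2.0*S.bond_k2[b]*dd + 4.0*S.bond_k4[b]*dd*dd*dd;
    double s = -dUdr / r;
    fadd(f, i, d, s); fadd(f, j, d, -s);
  }

  // ---- angles: U = k (theta - theta0)^2
  const int na = (int)S.angles.size() / 3;
  for (int a = 0; a < na; ++a) {
    int i = S.angles[3*a], j = S.angles[3*a+1], k = S.angles[3*a+2];
    if (skip_frozen && S.frozen[i] && S.frozen[j] && S.frozen[k]) continue;
    double rij[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    double rkj[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
    double li = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double lk = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    if (li < 1e-9 || lk < 1e-9)
      stop("coincident bonded beads (angle at %d)", j + 1);
    double c = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (li*lk);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - S.ang_t0[a];
    out.comp[S.ang_comp[a]] += S.ang_k[a]*dth*dth;
    double sth = std::sqrt(1.0 - c*c);
    if (sth < 1e-8) continue;   // force ill-defined exactly at 0/pi
    double coef = 2.0 * S.ang_k[a] * dth / sth;  // = dU/dtheta / sin(theta)
    // dc/dri and dc/drk
    for (int d = 0; d < 3; ++d) {
      double dci = rkj[d]/(li*lk) - c*rij[d]/(li*li);
      double dck = rij[d]/(li*lk) - c*rkj[d]/(lk*lk);
      double fi = coef * dci;
      double fk = coef * dck;
      f[3*i+d] += fi;
      f[3*k+d] += fk;
      f[3*j+d] -= fi + fk;
    }
  }

  // ---- dihedrals: U = k1 (1 - cos(phi - phi0)) + k3 (1 - cos 3(phi - phi0))
  const int nd = (int)S.dihs.size() / 4;
  for (int t = 0; t < nd; ++t) {
    int i = S.dihs[4*t], j = S.dihs[4*t+1], k = S.dihs[4*t+2], l = S.dihs[4*t+3];
    if (skip_frozen && S.frozen[i] && S.frozen[j] && S.frozen[k] && S.frozen[l])
      continue;
    double b1[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
    double b2[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
    double b3[3] = {x[3*l]-x[3*k], x[3*l+1]-x[3*k+1], x[3*l+2]-x[3*k+2]};
    double m[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                   b1[0]*b2[1]-b1[1]*b2[0]};
    double nn[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double m2 = m[0]*m[0]+m[1]*m[1]+m[2]*m[2];
    double n2 = nn[0]*nn[0]+nn[1]*nn[1]+nn[2]*nn[2];
    double lb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (m2 < 1e-12 || n2 < 1e-12 || lb2 < 1e-9) continue;
    double mxn[3] = {m[1]*nn[2]-m[2]*nn[1], m[2]*nn[0]-m[0]*nn[2],
                     m[0]*nn[1]-m[1]*nn[0]};
    double sinp = (mxn[0]*b2[0]+mxn[1]*b2[1]+mxn[2]*b2[2]) / lb2;
    double cosp = m[0]*nn[0]+m[1]*nn[1]+m[2]*nn[2];
    double phi = std::atan2(sinp, cosp);
    double dphi = phi - S.dih_phi0[t];
    out.comp[S.dih_comp[t]] +=
      S.dih_k1[t]*(1.0-std::cos(dphi)) + S.dih_k3[t]*(1.0-std::cos(3.0*dphi));
    double dU = S.dih_k1[t]*std::sin(dphi) + 3.0*S.dih_k3[t]*std::sin(3.0*dphi);
    // F_i = -dU dphi/dr_i with dphi/dr_i = -(|b2|/|m|^2) m,
    // dphi/dr_l = (|b2|/|n|^2) n, dphi/dr_j = -(1+t) dphi/dr_i + s dphi/dr_l
    double fi[3], fl[3];
    for (int d = 0; d < 3; ++d) {
      fi[d] =  dU * lb2 / m2 * m[d];
      fl[d] = -dU * lb2 / n2 * nn[d];
    }
    double tb = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (lb2*lb2);
    double sb = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (lb2*lb2);
    for (int d = 0; d < 3; ++d) {
      double fj = -(1.0 + tb)*fi[d] + sb*fl[d];
      double fk = -(fi[d] + fj + fl[d]);
      f[3*i+d] += fi[d];
      f[3*j+d] += fj;
      f[3*k+d] += fk;
      f[3*l+d] += fl[d];
    }
  }

  // ---- fixed 12-10 wells (stacking, WC pairing, protein native contacts)
  const int n1210 = (int)S.p1210.size() / 2;
  for (int p = 0; p < n1210; ++p) {
    int i = S.p1210[2*p], j = S.p1210[2*p+1];
    if (skip_frozen && S.frozen[i] && S.frozen[j]) continue;
    double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    min_image(d, S.box);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    double r0 = S.p1210_r0[p], eps = S.p1210_eps[p];
    double re = std::max(r, 0.6*r0);     // soft core for integrator safety
    double q = r0/re, q2 = q*q, q10 = q2*q2*q2*q2*q2, q12 = q10*q2;
    out.comp[S.p1210_comp[p]] += eps*(5.0*q12 - 6.0*q10);
    double dUdr = (60.0*eps/re) * (q10 - q12);
    if (r > 1e-9) {
      double s = -dUdr / r;
      fadd(f, i, d, s); fadd(f, j, d, -s);
    }
  }

  // ---- fixed 12-6 wells (specific + sequence non-specific)
  // "soft attractive": 12-6 tail for r > r0, flat -eps core below r0
  // (sterics are handled by the separate excluded-volume term), energy
  // shifted to zero at the per-pair cutoff
  const int n126 = (int)S.p126.size() / 2;
  for (int p = 0; p < n126; ++p) {
    int i = S.p126[2*p], j = S.p126[2*p+1];
    if (skip_frozen && S.frozen[i] && S.frozen[j]) continue;
    double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    min_image(d, S.box);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    double rc = S.p126_cut[p];
    if (r >= rc) continue;
    double r0 = S.p126_r0[p], eps = S.p126_eps[p];
    double qc = r0/rc, qc2 = qc*qc, qc6 = qc2*qc2*qc2;
    double ushift = eps*(qc6*qc6 - 2.0*qc6);
    if (r <= r0) {
      out.comp[S.p126_comp[p]] += -eps - ushift;   // flat core, zero force
      continue;
    }
    double q = r0/r, q2 = q*q, q6 = q2*q2*q2, q12 = q6*q6;
    out.comp[S.p126_comp[p]] += eps*(q12 - 2.0*q6) - ushift;
    double dUdr = (12.0*eps/r) * (q6 - q12);
    double s = -dUdr / r;
    fadd(f, i, d, s); fadd(f, j, d, -s);
  }

  // ---- excluded volume (WCA), per-pair sigma = (sigma_i + sigma_j)/2
  const int nev = (int)L.ev.size() / 2;
  for (int p = 0; p < nev; ++p) {
    int i = L.ev[2*p], j = L.ev[2*p+1];
    double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    min_image(d, S.box);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    double sig = 0.5*(S.sigma[i]+S.sigma[j]);
    double rc = 1.122462048309373 * sig;
    if (r2 >= rc*rc) continue;
    double r = std::sqrt(r2);
    double re = std::max(r, 0.75*sig);
    double q = sig/re, q2 = q*q, q6 = q2*q2*q2, q12 = q6*q6;
    double u = 4.0*S.ev_eps*(q12 - q6) + S.ev_eps;
    // intra-protein repulsion is a protein-model term, everything else is E_ev
    int comp = (S.mol[i] == 1 && S.mol[j] == 1) ? C_PRO_NONNATIVE : C_EV;
    out.comp[comp] += u;
    double dUdr = (24.0*S.ev_eps/re) * (q6 - 2.0*q12);
    if (r > 1e-9) {
      double s = -dUdr / r;
      fadd(f, i, d, s); fadd(f, j, d, -s);
    }
  }

  // ---- Debye-Huckel electrostatics, shifted at cutoff
  const double lam = S.lambda, rcut = S.elec_cut;
  const double shift_unit = fast_exp(-rcut/lam) / rcut;
  const int nel = (int)L.elec.size() / 2;
  const double rcut2 = rcut * rcut;
  const double inv_lam = 1.0 / lam;
  double e_el = 0.0;
  for (int p = 0; p < nel; ++p) {
    int i = L.elec[2*p], j = L.elec[2*p+1];
    double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    min_image(d, S.box);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= rcut2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-9) stop("overlapping charges");
    double pref = L.elec_pref[p];
    double e = fast_exp(-r * inv_lam);
    double invr = 1.0 / r;
    e_el += pref * (e * invr - shift_unit);
    double dUdr = -pref * e * (inv_lam * invr + invr * invr);
    double s = -dUdr * invr;
    fadd(f, i, d, s); fadd(f, j, d, -s);
  }
  out.comp[C_ELEC] += e_el;

  // ---- solvent-induced cohesion between base beads
  // attractive branch of a Morse-type well; the repulsive branch is
  // delegated to excluded volume (U = -eps for r < r0), shifted at cutoff
  if (S.solv_on) {
    double ac = S.solv_alpha * (S.solv_cut - S.solv_r0);
    double ec = 1.0 - fast_exp(-ac);
    double ushift = S.solv_eps * (ec*ec - 1.0);
    const int ns = (int)L.solv.size() / 2;
    for (int p = 0; p < ns; ++p) {
      int i = L.solv[2*p], j = L.solv[2*p+1];
      double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
      min_image(d, S.box);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (r2 >= S.solv_cut*S.solv_cut) continue;
      double r = std::sqrt(r2);
      if (r <= S.solv_r0) {
        out.comp[C_SOLVENT] += -S.solv_eps - ushift;
        continue;                          // flat: zero force
      }
      double ex = fast_exp(-S.solv_alpha*(r - S.solv_r0));
      double om = 1.0 - ex;
      out.comp[C_SOLVENT] += S.solv_eps*(om*om - 1.0) - ushift;
      double dUdr = 2.0*S.solv_eps*S.solv_alpha*ex*om;
      double s = -dUdr / r;
      fadd(f, i, d, s); fadd(f, j, d, -s);
    }
  }

  // ---- cylindrical cage on base-pair centers
  if (S.cage_on) {
    const int np = (int)S.cage_pairs.size() / 2;
    for (int p = 0; p < np; ++p) {
      int i = S.cage_pairs[2*p], j = S.cage_pairs[2*p+1];
      double c[3] = {0.5*(x[3*i]+x[3*j]), 0.5*(x[3*i+1]+x[3*j+1]),
                     0.5*(x[3*i+2]+x[3*j+2])};
      double w[3] = {c[0]-S.axis_a[0], c[1]-S.axis_a[1], c[2]-S.axis_a[2]};
      double proj = w[0]*S.axis_u[0] + w[1]*S.axis_u[1] + w[2]*S.axis_u[2];
      double dv[3] = {w[0]-proj*S.axis_u[0], w[1]-proj*S.axis_u[1],
                      w[2]-proj*S.axis_u[2]};
      double di = std::sqrt(dv[0]*dv[0]+dv[1]*dv[1]+dv[2]*dv[2]);
      out.cage_maxd = std::max(out.cage_maxd, di);
      if (di >= S.cage_R - 0.01) { out.cage_violation = true; }
      double g = S.cage_R - di;
      if (g >= 0.5*S.cage_C) continue;     // H(C/2 - (R - d)) = 0
      if (g <= 1e-6) g = 1e-6;             // wall guard (violation flagged)
      double xq = S.cage_C / (2.0*g);
      double u = S.cage_K*(xq*xq*xq*xq - 2.0*xq*xq - 1.0);
      if (S.cage_shift) u += 2.0*S.cage_K;
      out.comp[C_CAGE] += u;
      double dUdd = 4.0*S.cage_K*xq*xq*(xq*xq - 1.0)/g;
      if (di > 1e-9) {
        double s = -dUdd / di * 0.5;       // split over the two base beads
        fadd(f, i, dv, s);
        fadd(f, j, dv, s);
      }
    }
  }

  // ---- harmonic restraints on beads / bead-pair midpoints
  const int nr = (int)S.res_i.size();
  for (int t = 0; t < nr; ++t) {
    int i = S.res_i[t], j = S.res_j[t];
    double p[3], w;
    if (i == j) {
      p[0]=x[3*i]; p[1]=x[3*i+1]; p[2]=x[3*i+2]; w = 1.0;
    } else {
      p[0]=0.5*(x[3*i]+x[3*j]); p[1]=0.5*(x[3*i+1]+x[3*j+1]);
      p[2]=0.5*(x[3*i+2]+x[3*j+2]); w = 0.5;
    }
    double d[3] = {p[0]-S.res_p[3*t], p[1]-S.res_p[3*t+1], p[2]-S.res_p[3*t+2]};
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    out.comp[C_RESTRAINT] += S.res_k[t]*r2;
    for (int dd = 0; dd < 3; ++dd) {
      double fr = -2.0*S.res_k[t]*d[dd]*w;
      f[3*i+dd] += fr;
      if (j != i) f[3*j+dd] += fr;
    }
  }

  // zero forces on frozen beads
  for (int i = 0; i < n; ++i)
    if (S.frozen[i]) { f[3*i]=0; f[3*i+1]=0; f[3*i+2]=0; }
}


// far-field electrostatics (multiple-timestep slot): forces + energy
static void eval_far(const Sys& S, const double* x, const NList& L,
                     std::vector<double>& farF, double& far_e) {
  farF.assign(3 * S.n, 0.0);
  far_e = 0.0;
  const double lam = S.lambda, rcut = S.elec_cut;
  const double shift_unit = fast_exp(-rcut/lam) / rcut;
  const double rcut2 = rcut * rcut, inv_lam = 1.0 / lam;
  const int nel = (int)L.elec_far.size() / 2;
  for (int p = 0; p < nel; ++p) {
    int i = L.elec_far[2*p], j = L.elec_far[2*p+1];
    double d[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    min_image(d, S.box);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= rcut2) continue;
    double r = std::sqrt(r2);
    double pref = L.elec_far_pref[p];
    double e = fast_exp(-r * inv_lam);
    double invr = 1.0 / r;
    far_e += pref * (e * invr - shift_unit);
    double s = pref * e * (inv_lam * invr + invr * invr) * invr;
    farF[3*i] += s*d[0]; farF[3*i+1] += s*d[1]; farF[3*i+2] += s*d[2];
    farF[3*j] -= s*d[0]; farF[3*j+1] -= s*d[1]; farF[3*j+2] -= s*d[2];
  }
  for (int i = 0; i < S.n; ++i)
    if (S.frozen[i]) { farF[3*i]=0; farF[3*i+1]=0; farF[3*i+2]=0; }
}

// ---------------------------------------------------------------------------
// exported: single-point energy + forces
// ---------------------------------------------------------------------------
static CharacterVector comp_names() {
  return CharacterVector::create(
    "dna_bond", "dna_angle", "dna_dihedral", "stacking", "pairing", "solvent",
    "excluded_volume", "electrostatic", "cage", "restraint", "protein_bond",
    "protein_angle", "protein_dihedral", "protein_native", "protein_nonnative",
    "specific", "nonspecific");
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys, NumericMatrix coords) {
  Sys S = unpack(sys);
  if (coords.nrow() != S.n) stop("coords row count != system size");
  std::vector<double> x(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  NList L;
  build_nlist(S, x.data(), 0.0, false, L);
  ForceOut out;
  eval_forces(S, x.data(), L, false, out);
  if (S.cage_on && out.cage_maxd >= S.cage_R)
    stop("base-pair center at or beyond cage wall (d >= R)");
  NumericVector comps(N_COMP);
  comps.attr("names") = comp_names();
  double tot = 0.0;
  for (int c = 0; c < N_COMP; ++c) { comps[c] = out.comp[c]; tot += out.comp[c]; }
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = out.f[3*i+d];
  return List::create(_["components"] = comps, _["total"] = tot,
                      _["forces"] = fm);
}

// ---------------------------------------------------------------------------
// exported: BAOAB Langevin integrator
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_langevin(List sys, NumericMatrix coords, Nullable<NumericMatrix> vel,
                      int nsteps, double dt, double gamma, double kT,
                      double seed, int stride, double skin, int check_every,
                      double e_abort, double mts_r, int mts_every) {
  Sys S = unpack(sys);
  const int n = S.n;
  if (coords.nrow() != n) stop("coords row count != system size");
  std::vector<double> x(3*n), v(3*n, 0.0), xref(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);

  XRng rng((uint64_t)seed);
  if (vel.isNotNull()) {
    NumericMatrix vm(vel);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3*i+d] = vm(i, d);
  } else if (kT > 0.0) {
    double sv = std::sqrt(kT);            // mass = 1
    for (int i = 0; i < n; ++i)
      if (!S.frozen[i])
        for (int d = 0; d < 3; ++d) v[3*i+d] = sv * rng.norm();
  }
  for (int i = 0; i < n; ++i)
    if (S.frozen[i]) { v[3*i]=0; v[3*i+1]=0; v[3*i+2]=0; }

  NList L;
  build_nlist(S, x.data(), skin, true, L, mts_r);
  xref = x;
  std::vector<double> farF(3*n, 0.0);
  double far_e = 0.0;
  bool use_mts = mts_r > 0.0;
  if (use_mts) eval_far(S, x.data(), L, farF, far_e);
  ForceOut F;
  eval_forces(S, x.data(), L, true, F);
  if (use_mts) {
    for (int q = 0; q < 3*n; ++q) F.f[q] += farF[q];
    F.comp[C_ELEC] += far_e;
  }

  const int nf = nsteps / stride + 1;
  NumericVector frames((R_xlen_t)n * 3 * nf);
  frames.attr("dim") = IntegerVector::create(n, 3, nf);
  NumericMatrix energies(nf, N_COMP + 2);   // + kinetic, + total potential

  int n_free = 0;
  for (int i = 0; i < n; ++i) if (!S.frozen[i]) ++n_free;

  long n_reject = 0, n_rebuild = 0;
  int fidx = 0;
  auto capture = [&](int fi) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[(R_xlen_t)fi * 3 * n + (R_xlen_t)d * n + i] = x[3*i+d];
    double pot = 0.0;
    for (int c = 0; c < N_COMP; ++c) {
      energies(fi, c) = F.comp[c];
      pot += F.comp[c];
    }
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      if (!S.frozen[i])
        ke += 0.5*(v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    energies(fi, N_COMP) = ke;
    energies(fi, N_COMP + 1) = pot;
  };
  capture(fidx++);

  const bool save_state = S.cage_on;
  std::vector<double> xs, vs;
  if (save_state) { xs.resize(3*n); vs.resize(3*n); }

  for (int step = 0; step < nsteps; ++step) {
    double dt_try = dt;
    int attempt = 0;
    if (save_state) { xs = x; vs = v; }
    for (;;) {
      double c1 = (gamma > 0.0) ? std::exp(-gamma * dt_try) : 1.0;
      double c2 = (kT > 0.0) ? std::sqrt((1.0 - c1*c1) * kT) : 0.0;
      // B
      for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
        v[3*i]   += 0.5*dt_try*F.f[3*i];
        v[3*i+1] += 0.5*dt_try*F.f[3*i+1];
        v[3*i+2] += 0.5*dt_try*F.f[3*i+2];
      }
      // A
      for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
        x[3*i]   += 0.5*dt_try*v[3*i];
        x[3*i+1] += 0.5*dt_try*v[3*i+1];
        x[3*i+2] += 0.5*dt_try*v[3*i+2];
      }
      // O
      if (gamma > 0.0) {
        for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
          v[3*i]   = c1*v[3*i]   + c2*rng.norm();
          v[3*i+1] = c1*v[3*i+1] + c2*rng.norm();
          v[3*i+2] = c1*v[3*i+2] + c2*rng.norm();
        }
      }
      // A
      for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
        x[3*i]   += 0.5*dt_try*v[3*i];
        x[3*i+1] += 0.5*dt_try*v[3*i+1];
        x[3*i+2] += 0.5*dt_try*v[3*i+2];
      }
      // neighbour list maintenance
      if ((step + 1) % check_every == 0) {
        double md2 = 0.0;
        for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
          double dx = x[3*i]-xref[3*i], dy = x[3*i+1]-xref[3*i+1],
                 dz = x[3*i+2]-xref[3*i+2];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 > md2) md2 = d2;
        }
        if (!std::isfinite(md2))
          stop("coordinate divergence at step %d (check dt / initial overlap)",
               step + 1);
        if (md2 > 0.25*skin*skin) {
          build_nlist(S, x.data(), skin, true, L, mts_r);
          xref = x;
          ++n_rebuild;
          if (use_mts) eval_far(S, x.data(), L, farF, far_e);
        }
      }
      // B (with fresh forces)
      if (use_mts && (step + 1) % mts_every == 0)
        eval_far(S, x.data(), L, farF, far_e);
      eval_forces(S, x.data(), L, true, F);
      if (use_mts) {
        for (int q = 0; q < 3*n; ++q) F.f[q] += farF[q];
        F.comp[C_ELEC] += far_e;
      }
      if (S.cage_on && F.cage_violation) {
        // step rejected: wall overshoot; retake with halved dt
        if (++attempt > 8)
          stop("cage wall overshoot persisted after 8 dt halvings at step %d",
               step + 1);
        x = xs; v = vs;
        dt_try *= 0.5;
        ++n_reject;
        eval_forces(S, x.data(), L, true, F);
        if (use_mts) {
          for (int q = 0; q < 3*n; ++q) F.f[q] += farF[q];
          F.comp[C_ELEC] += far_e;
        }
        continue;
      }
      for (int i = 0; i < n; ++i) if (!S.frozen[i]) {
        v[3*i]   += 0.5*dt_try*F.f[3*i];
        v[3*i+1] += 0.5*dt_try*F.f[3*i+1];
        v[3*i+2] += 0.5*dt_try*F.f[3*i+2];
      }
      break;
    }
    if ((step + 1) % stride == 0) {
      capture(fidx++);
      double pot = energies(fidx - 1, N_COMP + 1);
      if (!std::isfinite(pot) || std::fabs(pot) > e_abort)
        stop("energy divergence at step %d (|E| = %g)", step + 1, pot);
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { xout(i, d) = x[3*i+d]; vout(i, d) = v[3*i+d]; }

  CharacterVector en(N_COMP + 2);
  CharacterVector cn = comp_names();
  for (int c = 0; c < N_COMP; ++c) en[c] = cn[c];
  en[N_COMP] = "kinetic"; en[N_COMP + 1] = "potential";
  colnames(energies) = en;

  return List::create(
    _["frames"] = frames, _["energies"] = energies,
    _["final_coords"] = xout, _["final_vel"] = vout,
    _["n_reject"] = (double)n_reject, _["n_rebuild"] = (double)n_rebuild);
}
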