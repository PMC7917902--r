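// Compiled core: force-field evaluation, steepest-descent relaxation and the
// velocity-Verlet / collisional-thermostat MD engine.
//
// Units: Angstrom, picosecond, Dalton, kcal/mol.

#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static const double ECONV = 418.4;        // kcal/mol in Da*A^2/ps^2
static const double KBOLTZ = 0.0019872041; // kcal/mol/K

struct Sys {
  int N;
  std::vector<double> mass, q, eps, sig, seps;
  std::vector<int> b_i, b_j; std::vector<double> b0, kb;
  std::vector<int> a_i, a_j, a_k; std::vector<double> th0, kth;
  std::vector<int> d_i, d_j, d_k, d_l, d_mult;
  std::vector<double> d_amp, d_phase, d_cosph, d_sinph;
  std::unordered_set<long long> excl;
  std::unordered_set<long long> set14;
  double s14lj, s14qq, cutoff, qqc, qqslope;
  bool any_charge;
};

static inline long long pkey(int i, int j, int N) {
  if (i > j) std::swap(i, j);
  return (long long)i * N + j;
}

static Sys parse_sys(const List& sys) {
  Sys s;
  s.N = as<int>(sys["n"]);
  s.mass = as<std::vector<double>>(sys["mass"]);
  s.q = as<std::vector<double>>(sys["charge"]);
  s.eps = as<std::vector<double>>(sys["lj_eps"]);
  s.sig = as<std::vector<double>>(sys["lj_sigma"]);
  IntegerMatrix b = sys["bonds"];
  for (int r = 0; r < b.nrow(); ++r) { s.b_i.push_back(b(r,0)); s.b_j.push_back(b(r,1)); }
  s.b0 = as<std::vector<double>>(sys["b0"]);
  s.kb = as<std::vector<double>>(sys["kb"]);
  IntegerMatrix a = sys["angles"];
  for (int r = 0; r < a.nrow(); ++r) { s.a_i.push_back(a(r,0)); s.a_j.push_back(a(r,1)); s.a_k.push_back(a(r,2)); }
  s.th0 = as<std::vector<double>>(sys["theta0"]);
  s.kth = as<std::vector<double>>(sys["ktheta"]);
  IntegerMatrix d = sys["dihedrals"];
  for (int r = 0; r < d.nrow(); ++r) {
    s.d_i.push_back(d(r,0)); s.d_j.push_back(d(r,1));
    s.d_k.push_back(d(r,2)); s.d_l.push_back(d(r,3));
  }
  s.d_amp = as<std::vector<double>>(sys["d_amp"]);
  s.d_mult = as<std::vector<int>>(sys["d_mult"]);
  s.d_phase = as<std::vector<double>>(sys["d_phase"]);
  for (double ph : s.d_phase) {
    s.d_cosph.push_back(std::cos(ph));
    s.d_sinph.push_back(std::sin(ph));
  }
  IntegerMatrix ex = sys["excl"];
  for (int r = 0; r < ex.nrow(); ++r) s.excl.insert(pkey(ex(r,0), ex(r,1), s.N));
  IntegerMatrix p14 = sys["pairs14"];
  for (int r = 0; r < p14.nrow(); ++r) s.set14.insert(pkey(p14(r,0), p14(r,1), s.N));
  s.s14lj = as<double>(sys["scale14_lj"]);
  s.s14qq = as<double>(sys["scale14_qq"]);
  s.cutoff = as<double>(sys["cutoff"]);
  s.qqc = as<double>(sys["qq_coupling"]);
  s.qqslope = as<double>(sys["qq_slope"]);
  s.any_charge = false;
  for (double qi : s.q) if (qi != 0.0) { s.any_charge = true; break; }
  s.seps.resize(s.N);
  for (int i = 0; i < s.N; ++i) s.seps[i] = std::sqrt(s.eps[i]);
  return s;
}

struct Wall {
  bool on; double eps, rmin, cutoff;
};

static Wall parse_wall(const NumericVector& w) {
  Wall wall; wall.on = w.size() == 3;
  if (wall.on) { wall.eps = w[0]; wall.rmin = w[1]; wall.cutoff = w[2]; }
  return wall;
}

// E terms: 0 U12, 1 U13, 2 U14, 3 Uvw, 4 Uqq, 5 Uads
static void bonded_terms(const std::vector<double>& x, const Sys& s,
                         double* E, std::vector<double>& F) {
  // bonds
  for (size_t r = 0; r < s.b_i.size(); ++r) {
    int i = s.b_i[r], j = s.b_j[r];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double rr = std::sqrt(dx*dx + dy*dy + dz*dz);
    double db = rr - s.b0[r];
    E[0] += s.kb[r] * db * db;
    double fs = -2.0 * s.kb[r] * db / rr; // along (ri - rj) on atom i
    F[3*i] += fs*dx; F[3*i+1] += fs*dy; F[3*i+2] += fs*dz;
    F[3*j] -= fs*dx; F[3*j+1] -= fs*dy; F[3*j+2] -= fs*dz;
  }
  // angles
  for (size_t r = 0; r < s.a_i.size(); ++r) {
    int i = s.a_i[r], j = s.a_j[r], k = s.a_k[r];
    double ux = x[3*i]-x[3*j], uy = x[3*i+1]-x[3*j+1], uz = x[3*i+2]-x[3*j+2];
    double vx = x[3*k]-x[3*j], vy = x[3*k+1]-x[3*j+1], vz = x[3*k+2]-x[3*j+2];
    double ru = std::sqrt(ux*ux+uy*uy+uz*uz), rv = std::sqrt(vx*vx+vy*vy+vz*vz);
    double ct = (ux*vx+uy*vy+uz*vz)/(ru*rv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct*ct);
    if (st < 1e-8) st = 1e-8;
    double dth = th - s.th0[r];
    E[1] += s.kth[r] * dth * dth;
    double dUdth = 2.0 * s.kth[r] * dth;
    double gi[3], gk[3];
    double uh[3] = {ux/ru, uy/ru, uz/ru};
    double vh[3] = {vx/rv, vy/rv, vz/rv};
    for (int c = 0; c < 3; ++c) {
      gi[c] = (ct*uh[c] - vh[c]) / (ru*st);
      gk[c] = (ct*vh[c] - uh[c]) / (rv*st);
    }
    for (int c = 0; c < 3; ++c) {
      double fi = -dUdth * gi[c];
      double fk = -dUdth * gk[c];
      F[3*i+c] += fi;
      F[3*k+c] += fk;
      F[3*j+c] -= (fi + fk);
    }
  }
  // dihedrals
  for (size_t r = 0; r < s.d_i.size(); ++r) {
    int i = s.d_i[r], j = s.d_j[r], k = s.d_k[r], l = s.d_l[r];
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3*j+c] - x[3*i+c];
      b2[c] = x[3*k+c] - x[3*j+c];
      b3[c] = x[3*l+c] - x[3*k+c];
    }
    double m[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0]};
    double n[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0]};
    double m2 = m[0]*m[0]+m[1]*m[1]+m[2]*m[2];
    double n2 = n[0]*n[0]+n[1]*n[1]+n[2]*n[2];
    double rb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (m2 < 1e-12 || n2 < 1e-12) continue; // degenerate (collinear)
    double cx[3] = {m[1]*n[2]-m[2]*n[1], m[2]*n[0]-m[0]*n[2], m[0]*n[1]-m[1]*n[0]};
    double invmn = 1.0 / std::sqrt(m2 * n2);
    double sp = (cx[0]*b2[0]+cx[1]*b2[1]+cx[2]*b2[2]) / rb2 * invmn; // sin(phi)
    double cp = (m[0]*n[0]+m[1]*n[1]+m[2]*n[2]) * invmn;            // cos(phi)
    // multiple-angle identities avoid atan2/sin/cos in the hot loop
    double cnp, snp;
    switch (s.d_mult[r]) {
    case 1: cnp = cp; snp = sp; break;
    case 2: cnp = 2.0*cp*cp - 1.0; snp = 2.0*sp*cp; break;
    case 3: cnp = (4.0*cp*cp - 3.0)*cp; snp = (3.0 - 4.0*sp*sp)*sp; break;
    default: { double phi = std::atan2(sp, cp);
               cnp = std::cos(s.d_mult[r]*phi); snp = std::sin(s.d_mult[r]*phi); }
    }
    double cd = s.d_cosph[r], sd = s.d_sinph[r];
    E[2] += s.d_amp[r] * (1.0 + cnp*cd + snp*sd);
    double dUdphi = -s.d_amp[r] * s.d_mult[r] * (snp*cd - cnp*sd);
    double gi[3], gl[3], gj[3], gk[3];
    double p = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2])/(rb2*rb2);
    double qq = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2])/(rb2*rb2);
    for (int c = 0; c < 3; ++c) {
      gi[c] = -rb2 / m2 * m[c];
      gl[c] =  rb2 / n2 * n[c];
      gj[c] = -(1.0 + p)*gi[c] + qq*gl[c];
      gk[c] = p*gi[c] - (1.0 + qq)*gl[c];
    }
    for (int c = 0; c < 3; ++c) {
      F[3*i+c] -= dUdphi * gi[c];
      F[3*j+c] -= dUdphi * gj[c];
      F[3*k+c] -= dUdphi * gk[c];
      F[3*l+c] -= dUdphi * gl[c];
    }
  }
}

static inline void pair_interaction(const std::vector<double>& x, const Sys& s,
                                    int i, int j, double slj, double sqq,
                                    double* E, std::vector<double>& F) {
  double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
  double r2 = dx*dx + dy*dy + dz*dz;
  if (r2 > s.cutoff * s.cutoff) return;
  double eij = s.seps[i]*s.seps[j] * slj;
  double sg = 0.5*(s.sig[i]+s.sig[j]);
  double s2 = sg*sg/r2, s6 = s2*s2*s2, s12 = s6*s6;
  double rc2 = s.cutoff*s.cutoff;
  double fs = 0.0;
  if (eij != 0.0) {
    // truncated-and-shifted LJ: zero at the cutoff, so energy is conserved
    double c6 = sg*sg/rc2; c6 = c6*c6*c6;
    E[3] += 4.0*eij*(s12 - s6) - 4.0*eij*(c6*c6 - c6);
    fs += (48.0*eij*s12 - 24.0*eij*s6) / r2;
  }
  if (s.any_charge && s.q[i] != 0.0 && s.q[j] != 0.0) {
    double pre = s.qqc * s.q[i]*s.q[j] * sqq / s.qqslope;
    E[4] += pre * (1.0/r2 - 1.0/rc2);
    fs += 2.0*pre / (r2*r2);
  }
  F[3*i] += fs*dx; F[3*i+1] += fs*dy; F[3*i+2] += fs*dz;
  F[3*j] -= fs*dx; F[3*j+1] -= fs*dy; F[3*j+2] -= fs*dz;
}

static void nonbonded_full(const std::vector<double>& x, const Sys& s,
                           double* E, std::vector<double>& F) {
  for (int i = 0; i < s.N; ++i) {
    for (int j = i+1; j < s.N; ++j) {
      long long key = (long long)i * s.N + j;
      if (s.excl.count(key)) continue;
      double slj = 1.0, sqq = 1.0;
      if (s.set14.count(key)) { slj = s.s14lj; sqq = s.s14qq; }
      pair_interaction(x, s, i, j, slj, sqq, E, F);
    }
  }
}

static void wall_terms(const std::vector<double>& x, const Wall& w, int N,
                       double* E, std::vector<double>& F) {
  if (!w.on || w.eps == 0.0) return;
  for (int i = 0; i < N; ++i) {
    double z = x[3*i+2];
    if (z <= 0.0) stop("atom %d at z = %g penetrated the impenetrable plane", i+1, z);
    if (z > w.cutoff) continue;
    double a = w.rmin / z;
    double a3 = a*a*a, a9 = a3*a3*a3;
    E[5] += 0.5 * w.eps * (a9 - 3.0*a3);
    F[3*i+2] += 4.5 * w.eps / z * (a9 - a3);
  }
}

// Full energy/force evaluation with an O(N^2) non-bonded loop.
// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix coords, List sys, NumericVector wall) {
  Sys s = parse_sys(sys);
  Wall w = parse_wall(wall);
  int N = s.N;
  if (coords.nrow() != N) stop("coordinate/topology size mismatch");
  std::vector<double> x(3*N), F(3*N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = coords(i, c);
  double E[6] = {0,0,0,0,0,0};
  bonded_terms(x, s, E, F);
  nonbonded_full(x, s, E, F);
  if (w.on && w.eps > 0.0) {
    for (int i = 0; i < N; ++i)
      if (x[3*i+2] <= 0.0) stop("z <= 0: atom penetrated the impenetrable plane");
  }
  wall_terms(x, w, N, E, F);
  NumericMatrix Fout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = F[3*i+c];
  NumericVector en = NumericVector::create(
    _["U12"] = E[0], _["U13"] = E[1], _["U14"] = E[2],
    _["Uvw"] = E[3], _["Uqq"] = E[4], _["U_ads"] = E[5]);
  return List::create(_["energy"] = en, _["forces"] = Fout);
}

// ---- neighbour list ------------------------------------------------------

// per-pair constants are frozen into the list at build time so the per-step
// loop needs no lookups, no sqrt and a single division per pair
struct NPair { int i, j; double eij4, sg2, qpre, shift_lj; };

// all non-excluded pairs with their interaction constants; built once so
// neighbour-list rebuilds are a plain distance filter (no hashing)
static void build_master_pairs(const Sys& s, std::vector<NPair>& master) {
  master.clear();
  double rc2 = s.cutoff * s.cutoff;
  for (int i = 0; i < s.N; ++i) {
    for (int j = i+1; j < s.N; ++j) {
      long long key = (long long)i * s.N + j;
      if (s.excl.count(key)) continue;
      double slj = 1.0, sqq = 1.0;
      if (s.set14.count(key)) { slj = s.s14lj; sqq = s.s14qq; }
      NPair p; p.i = i; p.j = j;
      double eij = s.seps[i]*s.seps[j] * slj;
      double sg = 0.5*(s.sig[i]+s.sig[j]);
      p.eij4 = 4.0*eij;
      p.sg2 = sg*sg;
      double c6 = p.sg2/rc2; c6 = c6*c6*c6;
      p.shift_lj = 4.0*eij*(c6*c6 - c6);
      p.qpre = (s.any_charge && s.q[i] != 0.0 && s.q[j] != 0.0)
        ? s.qqc * s.q[i]*s.q[j] * sqq / s.qqslope : 0.0;
      master.push_back(p);
    }
  }
}

static void build_nlist(const std::vector<double>& x, const Sys& s,
                        double skin, const std::vector<NPair>& master,
                        std::vector<NPair>& nl, std::vector<double>& xref) {
  nl.clear();
  double rl = s.cutoff + skin, rl2 = rl*rl;
  for (const NPair& p : master) {
    double dx = x[3*p.i]-x[3*p.j], dy = x[3*p.i+1]-x[3*p.j+1],
           dz = x[3*p.i+2]-x[3*p.j+2];
    if (dx*dx+dy*dy+dz*dz <= rl2) nl.push_back(p);
  }
  xref = x;
}

static bool nlist_stale(const std::vector<double>& x,
                        const std::vector<double>& xref, double skin) {
  double lim2 = 0.25 * skin * skin; // half-skin displacement criterion
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i]-xref[i], dy = x[i+1]-xref[i+1], dz = x[i+2]-xref[i+2];
    if (dx*dx+dy*dy+dz*dz > lim2) return true;
  }
  return false;
}

static void compute_forces_nl(const std::vector<double>& x, const Sys& s,
                              const Wall& w, const std::vector<NPair>& nl,
                              double* E, std::vector<double>& F) {
  for (int t = 0; t < 6; ++t) E[t] = 0.0;
  std::fill(F.begin(), F.end(), 0.0);
  bonded_terms(x, s, E, F);
  double rc2 = s.cutoff * s.cutoff, invrc2 = 1.0/rc2;
  double Evw = 0.0, Eqq = 0.0;
  // the list is sorted by i, so the i-side force accumulates in registers
  size_t idx = 0, M = nl.size();
  while (idx < M) {
    int i = nl[idx].i;
    double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
    double fix = 0.0, fiy = 0.0, fiz = 0.0;
    do {
      const NPair& p = nl[idx];
      int j = p.j;
      double dx = xi-x[3*j], dy = yi-x[3*j+1], dz = zi-x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 <= rc2) {
        double inv = 1.0/r2;
        double s2 = p.sg2*inv, s6 = s2*s2*s2, s12 = s6*s6;
        Evw += p.eij4*(s12 - s6) - p.shift_lj;
        double fs = p.eij4*(12.0*s12 - 6.0*s6)*inv;
        if (p.qpre != 0.0) {
          Eqq += p.qpre*(inv - invrc2);
          fs += 2.0*p.qpre*inv*inv;
        }
        fix += fs*dx; fiy += fs*dy; fiz += fs*dz;
        F[3*j] -= fs*dx; F[3*j+1] -= fs*dy; F[3*j+2] -= fs*dz;
      }
      ++idx;
    } while (idx < M && nl[idx].i == i);
    F[3*i] += fix; F[3*i+1] += fiy; F[3*i+2] += fiz;
  }
  E[3] += Evw; E[4] += Eqq;
  wall_terms(x, w, s.N, E, F);
}

// ---- steepest-descent relaxation ----------------------------------------

// [[Rcpp::export]]
List minimize_cpp(NumericMatrix coords, List sys, int maxit = 800,
                  double ftol = 5.0, double step0 = 0.05) {
  Sys s = parse_sys(sys);
  Wall w; w.on = false;
  int N = s.N;
  std::vector<double> x(3*N), F(3*N, 0.0), xt(3*N), Ft(3*N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = coords(i, c);
  double E[6], Et[6];
  std::fill(F.begin(), F.end(), 0.0);
  for (int t = 0; t < 6; ++t) E[t] = 0.0;
  bonded_terms(x, s, E, F);
  nonbonded_full(x, s, E, F);
  double e = E[0]+E[1]+E[2]+E[3]+E[4];
  double step = step0;
  int it = 0;
  for (; it < maxit; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < N; ++i) {
      double f2 = F[3*i]*F[3*i]+F[3*i+1]*F[3*i+1]+F[3*i+2]*F[3*i+2];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < ftol) break;
    // displace along forces; the largest per-atom move equals `step`
    for (size_t c = 0; c < x.size(); ++c) xt[c] = x[c] + step / fmax * F[c];
    std::fill(Ft.begin(), Ft.end(), 0.0);
    for (int t = 0; t < 6; ++t) Et[t] = 0.0;
    bonded_terms(xt, s, Et, Ft);
    nonbonded_full(xt, s, Et, Ft);
    double et = Et[0]+Et[1]+Et[2]+Et[3]+Et[4];
    if (et < e) {
      x = xt; F = Ft; e = et;
      step = std::min(step * 1.2, 0.5);
    } else {
      step *= 0.5;
      if (step < 1e-7) break;
    }
  }
  NumericMatrix xout(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) xout(i, c) = x[3*i+c];
  return List::create(_["coords"] = xout, _["energy"] = e,
                      _["iterations"] = it);
}

// ---- MD engine -----------------------------------------------------------

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix coords, NumericMatrix vels, List sys,
                NumericVector wall, double dt, int nsteps, int snap_every,
                bool thermostat, double temperature, double m0, double lambda,
                int seed, bool record_velocities) {
  Sys s = parse_sys(sys);
  Wall w = parse_wall(wall);
  int N = s.N;
  if (coords.nrow() != N || vels.nrow() != N) stop("size mismatch");
  std::vector<double> x(3*N), v(3*N), F(3*N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) { x[3*i+c] = coords(i,c); v[3*i+c] = vels(i,c); }

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::normal_distribution<double> rnorm01(0.0, 1.0);

  double skin = 1.5;
  std::vector<NPair> master, nl; std::vector<double> xref;
  build_master_pairs(s, master);
  build_nlist(x, s, skin, master, nl, xref);
  double E[6];
  compute_forces_nl(x, s, w, nl, E, F);

  int nsnap = nsteps / snap_every + 1;
  NumericVector traj(Dimension(N, 3, nsnap));
  NumericVector vtraj(record_velocities ? Dimension(N, 3, nsnap) : Dimension(1, 1, 1));
  NumericMatrix energies(nsnap, 8); // U12 U13 U14 Uvw Uqq U_ads KE T
  NumericVector times(nsnap);
  double pcoll = lambda * dt;
  double vfac = std::sqrt(KBOLTZ * temperature * ECONV / m0); // virtual-particle sd

  int isnap = 0;
  auto record = [&](int step) {
    times[isnap] = step * dt;
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      double v2 = v[3*i]*v[3*i]+v[3*i+1]*v[3*i+1]+v[3*i+2]*v[3*i+2];
      ke += 0.5 * s.mass[i] * v2;
    }
    ke /= ECONV;
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) {
        traj[(long long)isnap*3*N + (long long)c*N + i] = x[3*i+c];
        if (record_velocities)
          vtraj[(long long)isnap*3*N + (long long)c*N + i] = v[3*i+c];
      }
    for (int t = 0; t < 6; ++t) energies(isnap, t) = E[t];
    energies(isnap, 6) = ke;
    energies(isnap, 7) = 2.0 * ke / (3.0 * N * KBOLTZ);
    ++isnap;
  };
  record(0);

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {
      double hf = 0.5 * dt * ECONV / s.mass[i];
      for (int c = 0; c < 3; ++c) {
        v[3*i+c] += hf * F[3*i+c];
        x[3*i+c] += dt * v[3*i+c];
      }
    }
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(x[3*i]) || !std::isfinite(x[3*i+1]) || !std::isfinite(x[3*i+2]))
        stop("non-finite coordinates at step %d (atom %d): integration diverged", step, i+1);
      if (w.on && w.eps > 0.0 && x[3*i+2] <= 0.0)
        stop("atom %d reached z <= 0 at step %d: impenetrable-plane violation", i+1, step);
    }
    if (nlist_stale(x, xref, skin)) build_nlist(x, s, skin, master, nl, xref);
    compute_forces_nl(x, s, w, nl, E, F);
    for (int i = 0; i < N; ++i) {
      double hf = 0.5 * dt * ECONV / s.mass[i];
      for (int c = 0; c < 3; ++c) v[3*i+c] += hf * F[3*i+c];
    }
    if (thermostat && pcoll > 0.0) {
      for (int i = 0; i < N; ++i) {
        if (runif(rng) < pcoll) {
          double fac = 2.0 * m0 / (s.mass[i] + m0);
          for (int c = 0; c < 3; ++c) {
            double u = vfac * rnorm01(rng);
            v[3*i+c] += fac * (u - v[3*i+c]);
          }
        }
      }
    }
    if (step % snap_every == 0) record(step);
  }

  NumericMatrix xfin(N, 3), vfin(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) { xfin(i,c) = x[3*i+c]; vfin(i,c) = v[3*i+c]; }
  List out = List::create(
    _["times"] = times, _["coords"] = traj, _["energies"] = energies,
    _["final_coords"] = xfin, _["final_velocities"] = vfin);
  if (record_velocities) out["velocities"] = vtraj;
  return out;
}
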