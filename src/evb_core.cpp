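// Two-state EVB energy/force kernels and the leapfrog propagator.
// Units throughout: kcal/mol, Angstrom, fs, amu, elementary charge.
// Bond/angle/restraint convention is k*d^2 (NOT 0.5*k*d^2) so that force
// constants quoted in kcal mol^-1 A^-2 are used verbatim.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double COULOMB = 332.0636;      // kcal A / (mol e^2)
static const double KB      = 1.987204259e-3; // kcal/mol/K
static const double ACCEL   = 4.184e-4;       // (A/fs^2) per (kcal/mol/A / amu)

struct StateView {
  NumericMatrix bonds;   // i, j, form(0 harm,1 morse), p1, p2, p3
  NumericMatrix angles;  // i, j(center), k, ktheta, theta0(rad)
  NumericVector charges;
  NumericVector eps;
  NumericVector sigma;
  IntegerMatrix excl;    // 1-based excluded pairs
  double alpha;
};

static StateView as_state(const List& s) {
  StateView v;
  v.bonds   = as<NumericMatrix>(s["bonds"]);
  v.angles  = as<NumericMatrix>(s["angles"]);
  v.charges = as<NumericVector>(s["charges"]);
  v.eps     = as<NumericVector>(s["eps"]);
  v.sigma   = as<NumericVector>(s["sigma"]);
  v.excl    = as<IntegerMatrix>(s["excl"]);
  v.alpha   = as<double>(s["alpha"]);
  return v;
}

static std::vector<char> excl_mask(const StateView& s, int n) {
  std::vector<char> ex(n * n, 0);
  for (int p = 0; p < s.excl.nrow(); ++p) {
    int i = s.excl(p,0)-1, j = s.excl(p,1)-1;
    ex[i*n + j] = ex[j*n + i] = 1;
  }
  return ex;
}

// energy (and optionally forces, accumulated into F) of one diabatic state
static double state_eval(const NumericMatrix& x, const StateView& s,
                         const std::vector<char>& ex,
                         bool grad, NumericMatrix* F) {
  const int n = x.nrow();
  double e = s.alpha;

  // bonded terms
  for (int b = 0; b < s.bonds.nrow(); ++b) {
    int i = (int)s.bonds(b, 0) - 1, j = (int)s.bonds(b, 1) - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dedr;
    if ((int)s.bonds(b, 2) == 0) {              // harmonic k (r-r0)^2
      double k = s.bonds(b,3), r0 = s.bonds(b,4);
      e += k * (r - r0) * (r - r0);
      dedr = 2.0 * k * (r - r0);
    } else {                                    // Morse D (1-exp(-a(r-r0)))^2
      double D = s.bonds(b,3), a = s.bonds(b,4), r0 = s.bonds(b,5);
      double ex = std::exp(-a * (r - r0));
      e += D * (1.0 - ex) * (1.0 - ex);
      dedr = 2.0 * D * a * ex * (1.0 - ex);
    }
    if (grad && r > 1e-12) {
      double g = dedr / r;
      (*F)(i,0) -= g*dx; (*F)(i,1) -= g*dy; (*F)(i,2) -= g*dz;
      (*F)(j,0) += g*dx; (*F)(j,1) += g*dy; (*F)(j,2) += g*dz;
    }
  }

  // angle terms k (theta - theta0)^2, theta at central atom j
  for (int a = 0; a < s.angles.nrow(); ++a) {
    int i = (int)s.angles(a,0)-1, j = (int)s.angles(a,1)-1, k = (int)s.angles(a,2)-1;
    double kth = s.angles(a,3), th0 = s.angles(a,4);
    double r1x = x(i,0)-x(j,0), r1y = x(i,1)-x(j,1), r1z = x(i,2)-x(j,2);
    double r2x = x(k,0)-x(j,0), r2y = x(k,1)-x(j,1), r2z = x(k,2)-x(j,2);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    if (n1 < 1e-12 || n2 < 1e-12) continue;
    double c = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    e += kth * (th - th0) * (th - th0);
    if (grad) {
      double st = std::sqrt(1.0 - c*c);
      if (st < 1e-8) st = 1e-8;                 // near-collinear guard
      double dedth = 2.0 * kth * (th - th0);
      double f = dedth / st;                    // -dE/dcos * dcos/dr
      // dcos/dri, dcos/drk
      double gix = (r2x/(n1*n2)) - c * r1x/(n1*n1);
      double giy = (r2y/(n1*n2)) - c * r1y/(n1*n1);
      double giz = (r2z/(n1*n2)) - c * r1z/(n1*n1);
      double gkx = (r1x/(n1*n2)) - c * r2x/(n2*n2);
      double gky = (r1y/(n1*n2)) - c * r2y/(n2*n2);
      double gkz = (r1z/(n1*n2)) - c * r2z/(n2*n2);
      (*F)(i,0) += f*gix; (*F)(i,1) += f*giy; (*F)(i,2) += f*giz;
      (*F)(k,0) += f*gkx; (*F)(k,1) += f*gky; (*F)(k,2) += f*gkz;
      (*F)(j,0) -= f*(gix+gkx); (*F)(j,1) -= f*(giy+gky); (*F)(j,2) -= f*(giz+gkz);
    }
  }

  // nonbonded: all pairs except this state's exclusions (no cutoff)
  for (int i = 0; i < n; ++i) {
    for (int j = i+1; j < n; ++j) {
      if (ex[i*n + j]) continue;
      double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      if (r < 1e-12) continue;
      double dedr = 0.0;
      double qq = s.charges[i] * s.charges[j];
      if (qq != 0.0) {
        double ec = COULOMB * qq / r;
        e += ec;
        dedr += -ec / r;
      }
      double epsij = std::sqrt(s.eps[i] * s.eps[j]);
      if (epsij > 0.0) {
        double sij = 0.5 * (s.sigma[i] + s.sigma[j]);
        double s2 = sij*sij / r2;
        double sr6 = s2 * s2 * s2;
        double sr12 = sr6 * sr6;
        e += 4.0 * epsij * (sr12 - sr6);
        dedr += 4.0 * epsij * (-12.0*sr12 + 6.0*sr6) / r;
      }
      if (grad && dedr != 0.0) {
        double g = dedr / r;
        (*F)(i,0) -= g*dx; (*F)(i,1) -= g*dy; (*F)(i,2) -= g*dz;
        (*F)(j,0) += g*dx; (*F)(j,1) += g*dy; (*F)(j,2) += g*dz;
      }
    }
  }
  return e;
}

// ground-state mixing weight on state 1 (Hellmann-Feynman dEg/de1)
static double c1_sq_of(double e1, double e2, double h12) {
  double de = e1 - e2;
  double disc = std::sqrt(de*de + 4.0*h12*h12);
  if (disc < 1e-300) return 0.5;
  return 0.5 * (1.0 - de / disc);
}

// [[Rcpp::export]]
List cpp_diabatic(NumericMatrix xyz, List state1, List state2) {
  StateView s1 = as_state(state1), s2 = as_state(state2);
  int n = xyz.nrow();
  double e1 = state_eval(xyz, s1, excl_mask(s1, n), false, nullptr);
  double e2 = state_eval(xyz, s2, excl_mask(s2, n), false, nullptr);
  return List::create(_["e1"] = e1, _["e2"] = e2);
}

// surface: lambda in [0,1] -> mapping potential; surface < 0 -> adiabatic ground
// [[Rcpp::export]]
List cpp_evb_eval(NumericMatrix xyz, List state1, List state2, double h12,
                  double surface, bool forces) {
  StateView s1 = as_state(state1), s2 = as_state(state2);
  int n = xyz.nrow();
  NumericMatrix F1(n,3), F2(n,3), F(n,3);
  double e1 = state_eval(xyz, s1, excl_mask(s1, n), forces, &F1);
  double e2 = state_eval(xyz, s2, excl_mask(s2, n), forces, &F2);
  double de = e1 - e2;
  double disc = std::sqrt(de*de + 4.0*h12*h12);
  double eg = 0.5*(e1 + e2) - 0.5*disc;
  double c1s = c1_sq_of(e1, e2, h12);
  double w1, epot;
  if (surface >= 0.0) { w1 = 1.0 - surface; epot = (1.0-surface)*e1 + surface*e2; }
  else { w1 = c1s; epot = eg; }
  if (forces) {
    double w2 = 1.0 - w1;
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d)
      F(i,d) = w1*F1(i,d) + w2*F2(i,d);
  }
  return List::create(_["e1"] = e1, _["e2"] = e2, _["e_ground"] = eg,
                      _["gap"] = de, _["c1_sq"] = c1s, _["epot"] = epot,
                      _["forces"] = F);
}

// layered positional restraints + half-harmonic radial wall on listed atoms
static double restraint_eval(const NumericMatrix& x, const List& r,
                             bool grad, NumericMatrix* F) {
  NumericMatrix ref = as<NumericMatrix>(r["reference"]);
  NumericVector ctr = as<NumericVector>(r["center"]);
  double R = as<double>(r["radius"]);
  double ff = as<double>(r["free_fraction"]);
  double bk = as<double>(r["buffer_k"]);
  double ok = as<double>(r["outer_k"]);
  double wk = as<double>(r["wall_k"]);
  IntegerVector widx = as<IntegerVector>(r["wall_atoms"]); // 1-based
  NumericVector kevb = as<NumericVector>(r["k_atom"]);     // per-atom extra k (may be 0-length)
  double e = 0.0;
  int n = x.nrow();
  for (int i = 0; i < n; ++i) {
    double rdx = ref(i,0)-ctr[0], rdy = ref(i,1)-ctr[1], rdz = ref(i,2)-ctr[2];
    double dref = std::sqrt(rdx*rdx + rdy*rdy + rdz*rdz);
    double k = 0.0;
    if (dref > R) k = ok;
    else if (dref > ff * R) k = bk;
    if (kevb.size() == n) k += kevb[i];
    if (k > 0.0) {
      double dx = x(i,0)-ref(i,0), dy = x(i,1)-ref(i,1), dz = x(i,2)-ref(i,2);
      e += k * (dx*dx + dy*dy + dz*dz);
      if (grad) {
        (*F)(i,0) -= 2.0*k*dx; (*F)(i,1) -= 2.0*k*dy; (*F)(i,2) -= 2.0*k*dz;
      }
    }
  }
  for (int p = 0; p < widx.size(); ++p) {
    int i = widx[p] - 1;
    double dx = x(i,0)-ctr[0], dy = x(i,1)-ctr[1], dz = x(i,2)-ctr[2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d > R && d > 1e-12) {
      e += wk * (d - R) * (d - R);
      if (grad) {
        double g = 2.0 * wk * (d - R) / d;
        (*F)(i,0) -= g*dx; (*F)(i,1) -= g*dy; (*F)(i,2) -= g*dz;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_restraint(NumericMatrix xyz, List restraint) {
  int n = xyz.nrow();
  NumericMatrix F(n,3);
  double e = restraint_eval(xyz, restraint, true, &F);
  return List::create(_["energy"] = e, _["forces"] = F);
}

// Velocity-Verlet (leapfrog-equivalent) propagator with optional Langevin
// (BAOAB splitting) or Berendsen thermostat.
// thermostat: 0 none, 1 langevin (tparam = friction 1/fs),
//             2 berendsen (tparam = coupling time fs)
// [[Rcpp::export]]
List cpp_propagate(NumericMatrix xyz, NumericMatrix vel, NumericVector mass,
                   List state1, List state2, double h12, double surface,
                   Nullable<List> restraint, IntegerVector frozen,
                   int nsteps, double dt, double temperature,
                   int thermostat, double tparam,
                   int sample_every, int burn) {
  StateView s1 = as_state(state1), s2 = as_state(state2);
  int n = xyz.nrow();
  NumericMatrix x = clone(xyz), v = clone(vel);
  std::vector<bool> froz(n, false);
  for (int i = 0; i < frozen.size(); ++i) froz[frozen[i]-1] = true;
  int nfree = 0;
  for (int i = 0; i < n; ++i) if (!froz[i]) ++nfree;
  int ndof = 3 * nfree;
  bool has_rest = restraint.isNotNull();
  List rlist;
  if (has_rest) rlist = restraint.get();

  // force evaluation closure; exclusion masks built once per run
  std::vector<char> ex1 = excl_mask(s1, n), ex2 = excl_mask(s2, n);
  NumericMatrix F1(n,3), F2(n,3), F(n,3);
  double e1, e2, eg, epot;
  auto eval_forces = [&]() {
    std::fill(F1.begin(), F1.end(), 0.0);
    std::fill(F2.begin(), F2.end(), 0.0);
    e1 = state_eval(x, s1, ex1, true, &F1);
    e2 = state_eval(x, s2, ex2, true, &F2);
    double de = e1 - e2;
    double disc = std::sqrt(de*de + 4.0*h12*h12);
    eg = 0.5*(e1+e2) - 0.5*disc;
    double w1 = (surface >= 0.0) ? (1.0 - surface) : c1_sq_of(e1, e2, h12);
    double w2 = 1.0 - w1;
    epot = (surface >= 0.0) ? ((1.0-surface)*e1 + surface*e2) : eg;
    for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d)
      F(i,d) = w1*F1(i,d) + w2*F2(i,d);
    if (has_rest) epot += restraint_eval(x, rlist, true, &F);
    for (int i = 0; i < n; ++i) if (froz[i]) { F(i,0)=F(i,1)=F(i,2)=0.0; }
    if (!std::isfinite(epot)) stop("non-finite potential energy during propagation");
  };

  eval_forces();

  int nsamp = 0;
  for (int s = burn; s < nsteps; ++s) if ((s - burn) % sample_every == 0) ++nsamp;
  NumericMatrix out_x(nsamp, 3*n);
  NumericVector out_e1(nsamp), out_e2(nsamp), out_eg(nsamp),
                out_emap(nsamp), out_epot(nsamp), out_ke(nsamp);
  int si = 0;

  double c1 = 1.0, c2 = 0.0;
  if (thermostat == 1) {
    c1 = std::exp(-tparam * dt);
    c2 = std::sqrt(1.0 - c1*c1);
  }

  for (int step = 0; step < nsteps; ++step) {
    if (thermostat == 1) {
      // BAOAB: B (half kick), A (half drift), O, A, B + force eval
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        double a = ACCEL / mass[i];
        v(i,0) += 0.5*dt*F(i,0)*a; v(i,1) += 0.5*dt*F(i,1)*a; v(i,2) += 0.5*dt*F(i,2)*a;
        x(i,0) += 0.5*dt*v(i,0);   x(i,1) += 0.5*dt*v(i,1);   x(i,2) += 0.5*dt*v(i,2);
      }
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        double sv = std::sqrt(KB * temperature * ACCEL / mass[i]);
        v(i,0) = c1*v(i,0) + c2*sv*norm_rand();
        v(i,1) = c1*v(i,1) + c2*sv*norm_rand();
        v(i,2) = c1*v(i,2) + c2*sv*norm_rand();
      }
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        x(i,0) += 0.5*dt*v(i,0); x(i,1) += 0.5*dt*v(i,1); x(i,2) += 0.5*dt*v(i,2);
      }
      eval_forces();
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        double a = ACCEL / mass[i];
        v(i,0) += 0.5*dt*F(i,0)*a; v(i,1) += 0.5*dt*F(i,1)*a; v(i,2) += 0.5*dt*F(i,2)*a;
      }
    } else {
      // velocity Verlet
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        double a = ACCEL / mass[i];
        v(i,0) += 0.5*dt*F(i,0)*a; v(i,1) += 0.5*dt*F(i,1)*a; v(i,2) += 0.5*dt*F(i,2)*a;
        x(i,0) += dt*v(i,0); x(i,1) += dt*v(i,1); x(i,2) += dt*v(i,2);
      }
      eval_forces();
      for (int i = 0; i < n; ++i) if (!froz[i]) {
        double a = ACCEL / mass[i];
        v(i,0) += 0.5*dt*F(i,0)*a; v(i,1) += 0.5*dt*F(i,1)*a; v(i,2) += 0.5*dt*F(i,2)*a;
      }
      if (thermostat == 2 && temperature > 0) {
        double ke = 0.0;
        for (int i = 0; i < n; ++i) if (!froz[i])
          ke += 0.5 * mass[i] * (v(i,0)*v(i,0)+v(i,1)*v(i,1)+v(i,2)*v(i,2)) / ACCEL;
        double tinst = (ndof > 0) ? 2.0*ke/(ndof*KB) : 0.0;
        if (tinst > 1e-12) {
          double lam2 = 1.0 + (dt/tparam) * (temperature/tinst - 1.0);
          if (lam2 < 0.64) lam2 = 0.64;          // cap scaling at 0.8x
          if (lam2 > 1.5625) lam2 = 1.5625;      // and 1.25x per step
          double lam = std::sqrt(lam2);
          for (int i = 0; i < n; ++i) if (!froz[i]) {
            v(i,0) *= lam; v(i,1) *= lam; v(i,2) *= lam;
          }
        }
      }
    }

    if (step >= burn && (step - burn) % sample_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) if (!froz[i])
        ke += 0.5 * mass[i] * (v(i,0)*v(i,0)+v(i,1)*v(i,1)+v(i,2)*v(i,2)) / ACCEL;
      for (int i = 0; i < n; ++i) {
        out_x(si, 3*i) = x(i,0); out_x(si, 3*i+1) = x(i,1); out_x(si, 3*i+2) = x(i,2);
      }
      out_e1[si] = e1; out_e2[si] = e2; out_eg[si] = eg;
      out_emap[si] = (surface >= 0.0) ? ((1.0-surface)*e1 + surface*e2) : eg;
      out_epot[si] = epot; out_ke[si] = ke;
      ++si;
    }
  }

  return List::create(_["coords"] = out_x, _["e1"] = out_e1, _["e2"] = out_e2,
                      _["e_ground"] = out_eg, _["e_map"] = out_emap,
                      _["epot"] = out_epot, _["kinetic"] = out_ke,
                      _["xyz_final"] = x, _["vel_final"] = v,
                      _["ndof"] = ndof);
}
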