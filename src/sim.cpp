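// Individual-based core of the Helper-Manufacturer community simulator.
//
// The maturation loop follows the operator-splitting scheme of the model:
// within each time step dtau the chemicals (Resource R, Byproduct B) evolve
// with cell biomasses frozen at their start-of-step values, together with one
// cumulative growth integral per phenotype group (augmented ODE states); the
// integrals are then applied to individual cell lengths, Product is accrued
// from realized M biomass deltas, and stochastic death, division at length 2,
// and mutation of freshly divided cells follow in that order.
//
// All randomness goes through R's RNG (unif_rand), so a set.seed() on the R
// side makes every maturation exactly replayable.

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int SP_H = 1;
static const int SP_M = 2;

struct ChemPar {
  double cRM, cRH, cBM, B0inv; // B0inv = 1/B0 (0 => no Byproduct inhibition)
  bool excessB;                // Byproduct saturating (monoculture scenario)
};

struct Grp {
  int species;
  double gmax, affR, affB;
  double biomass;
  double integ; // int g dt over the step
};

// Monod growth with affinity parameterization: g = gmax * R*aff / (R*aff + 1).
// aff = 0 (null affinity, K -> Inf) gives 0.
static inline double monod(double R, double gmax, double aff) {
  if (R <= 0.0 || aff <= 0.0 || gmax <= 0.0) return 0.0;
  double x = R * aff;
  return gmax * x / (x + 1.0);
}

// Dual-substrate Mankad-Bungay growth.
static inline double mankad_bungay(double R, double B, double gmax,
                                   double affR, double affB) {
  if (gmax <= 0.0) return 0.0;
  double RM = R * affR, BM = B * affB;
  if (RM <= 0.0 || BM <= 0.0) return 0.0;
  return gmax * RM * BM / (RM + BM) * (1.0 / (RM + 1.0) + 1.0 / (BM + 1.0));
}

static inline double grp_rate(const Grp& g, double R, double B,
                              const ChemPar& cp) {
  if (g.species == SP_H) {
    double r = monod(R, g.gmax, g.affR);
    if (cp.B0inv > 0.0) r *= std::exp(-B * cp.B0inv);
    return r;
  }
  if (cp.excessB) return monod(R, g.gmax, g.affR);
  return mankad_bungay(R, B, g.gmax, g.affR, g.affB);
}

// RHS of the frozen-biomass chemical system plus per-group quadratures.
// y = (R, B, I_1, ..., I_nG)
static void chem_rhs(const std::vector<double>& y, std::vector<double>& dy,
                     const std::vector<Grp>& grps, const ChemPar& cp) {
  double R = y[0] > 0.0 ? y[0] : 0.0;
  double B = y[1] > 0.0 ? y[1] : 0.0;
  double dR = 0.0, dB = 0.0;
  for (size_t k = 0; k < grps.size(); ++k) {
    double g = grp_rate(grps[k], R, B, cp);
    dy[2 + k] = g;
    double flux = g * grps[k].biomass;
    if (grps[k].species == SP_H) {
      dR -= cp.cRH * flux;
      if (!cp.excessB) dB += flux;
    } else {
      dR -= cp.cRM * flux;
      if (!cp.excessB) dB -= cp.cBM * flux;
    }
  }
  dy[0] = dR;
  dy[1] = dB;
}

// Adaptive Dormand-Prince 5(4) over [0, dt]; error control on all states.
static void chem_step_core(double& R, double& B, std::vector<Grp>& grps,
                           double dt, const ChemPar& cp, double rtol,
                           double atol) {
  const size_t n = 2 + grps.size();
  std::vector<double> y(n, 0.0), yn(n), ye(n), tmp(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  y[0] = R;
  y[1] = B;

  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
  (void)c2; (void)c3; (void)c4; (void)c5;

  double t = 0.0, h = dt;
  int iter = 0;
  chem_rhs(y, k1, grps, cp);
  while (t < dt * (1.0 - 1e-14)) {
    if (++iter > 100000)
      stop("chemical step solver failed to converge (R=%g, B=%g, t=%g)",
           y[0], y[1], t);
    if (h > dt - t) h = dt - t;

    for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + h * a21 * k1[i];
    chem_rhs(tmp, k2, grps, cp);
    for (size_t i = 0; i < n; ++i)
      tmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    chem_rhs(tmp, k3, grps, cp);
    for (size_t i = 0; i < n; ++i)
      tmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    chem_rhs(tmp, k4, grps, cp);
    for (size_t i = 0; i < n; ++i)
      tmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                           a54 * k4[i]);
    chem_rhs(tmp, k5, grps, cp);
    for (size_t i = 0; i < n; ++i)
      tmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                           a64 * k4[i] + a65 * k5[i]);
    chem_rhs(tmp, k6, grps, cp);
    for (size_t i = 0; i < n; ++i)
      yn[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    chem_rhs(yn, k7, grps, cp);

    double err = 0.0;
    for (size_t i = 0; i < n; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yn[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);

    if (err <= 1.0) {
      t += h;
      y = yn;
      k1 = k7; // FSAL
    }
    double fac = 0.9 * std::pow(err > 1e-12 ? err : 1e-12, -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14 * dt)
      stop("chemical step solver step size underflow (R=%g, B=%g, t=%g)",
           y[0], y[1], t);
  }

  R = y[0] > 0.0 ? y[0] : 0.0;
  B = y[1] > 0.0 ? y[1] : 0.0;
  for (size_t k = 0; k < grps.size(); ++k) grps[k].integ = y[2 + k];
}

static ChemPar chempar_from_list(const List& fixed) {
  ChemPar cp;
  cp.cRM = as<double>(fixed["cRM"]);
  cp.cRH = as<double>(fixed["cRH"]);
  cp.cBM = as<double>(fixed["cBM"]);
  cp.B0inv = fixed.containsElementNamed("B0inv") ? as<double>(fixed["B0inv"])
                                                 : 0.0;
  cp.excessB = fixed.containsElementNamed("excessB")
                   ? as<bool>(fixed["excessB"])
                   : false;
  return cp;
}

// Chemical integration over one dtau with frozen per-group biomasses.
// Returns end-of-step R and B plus the per-group growth integrals.
// [[Rcpp::export]]
List chem_step_cpp(double R, double B, IntegerVector species,
                   NumericVector gmax, NumericVector affR, NumericVector affB,
                   NumericVector biomass, double dtau, List fixed,
                   double rtol = 1e-6, double atol = 1e-9) {
  int nG = species.size();
  std::vector<Grp> grps(nG);
  for (int k = 0; k < nG; ++k) {
    grps[k].species = species[k];
    grps[k].gmax = gmax[k];
    grps[k].affR = affR[k];
    grps[k].affB = NumericVector::is_na(affB[k]) ? 0.0 : affB[k];
    grps[k].biomass = biomass[k];
    grps[k].integ = 0.0;
  }
  ChemPar cp = chempar_from_list(fixed);
  chem_step_core(R, B, grps, dtau, cp, rtol, atol);
  NumericVector integ(nG);
  for (int k = 0; k < nG; ++k) integ[k] = grps[k].integ;
  return List::create(_["R"] = R, _["B"] = B, _["integrals"] = integ);
}

// Inverse-CDF draw of a relative mutation effect from the bilateral
// exponential distribution (truncated at -1 on the diminishing side).
static inline double sample_delta(double u2, double sp, double sm) {
  double trunc = std::exp(-1.0 / sm);
  double D = sp + sm * (1.0 - trunc);
  double C0 = sm * (1.0 - trunc) / D;
  if (u2 <= C0) return sm * std::log(u2 * D / sm + trunc);
  return -sp * std::log((1.0 - u2) * D / sp);
}

// [[Rcpp::export]]
NumericVector sample_delta_cpp(NumericVector u2, double s_plus,
                               double s_minus) {
  int n = u2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!(u2[i] > 0.0 && u2[i] < 1.0))
      stop("u2 must lie strictly inside (0, 1)");
    out[i] = sample_delta(u2[i], s_plus, s_minus);
  }
  return out;
}

struct MutPar {
  double Pmut, pnull, splus, sminus, g_epi, fP_init;
  bool mut_gH, mut_affHR, mut_gM, mut_affMR, mut_affMB, mut_fP;
};

static MutPar mutpar_from_list(const List& mut) {
  MutPar mp;
  mp.Pmut = as<double>(mut["P_mut"]);
  mp.pnull = as<double>(mut["p_null"]);
  mp.splus = as<double>(mut["s_plus"]);
  mp.sminus = as<double>(mut["s_minus"]);
  mp.g_epi = as<double>(mut["epistasis_g"]);
  mp.fP_init = as<double>(mut["fP_init"]);
  LogicalVector mm = mut["mutable_flags"]; // gHmax affHR gMmax affMR affMB fP
  mp.mut_gH = mm[0];
  mp.mut_affHR = mm[1];
  mp.mut_gM = mm[2];
  mp.mut_affMR = mm[3];
  mp.mut_affMB = mm[4];
  mp.mut_fP = mm[5];
  return mp;
}

// One phenotype value through the mutation kernel: null with probability
// p_null, otherwise multiplied by (1 + delta); clamped to [lo, hi].
// Draws exactly two uniforms on the non-null branch, one otherwise.
static inline double mutate_value(double v, double lo, double hi,
                                  double pnull, double sp, double sm) {
  double u1 = unif_rand();
  if (u1 < pnull) return 0.0;
  double u2 = unif_rand();
  // unif_rand() is strictly inside (0,1) for R's generators
  double d = sample_delta(u2, sp, sm);
  v *= (1.0 + d);
  if (v < lo) v = lo;
  if (v > hi) v = hi;
  return v;
}

static inline void epistatic_scales(double fP, const MutPar& mp, double& sp,
                                    double& sm) {
  sp = mp.splus;
  sm = mp.sminus;
  if (mp.g_epi > 0.0) {
    double fac = 1.0 + mp.g_epi * (fP / mp.fP_init - 1.0);
    if (fac <= 0.0)
      stop("epistasis factor produced non-positive mean effect (fP=%g)", fP);
    sp = mp.splus / fac;
    sm = mp.sminus * fac;
  }
}

struct Bounds {
  double gH_hi, affHR_hi, gM_hi, affMR_hi, affMB_hi, fP_hi;
};

static Bounds bounds_from_list(const List& b) {
  Bounds bb;
  bb.gH_hi = as<double>(b["gHmax"]);
  bb.affHR_hi = as<double>(b["affHR"]);
  bb.gM_hi = as<double>(b["gMmax"]);
  bb.affMR_hi = as<double>(b["affMR"]);
  bb.affMB_hi = as<double>(b["affMB"]);
  bb.fP_hi = as<double>(b["fP"]);
  return bb;
}

// Mutate one freshly divided cell in place. Phenotype order is canonical:
// H cells gmax, affR; M cells gmax, affR, affB, fP. One occurrence draw per
// mutable phenotype.
static inline void mutate_cell(int sp, double& gmax, double& affR,
                               double& affB, double& fP, const MutPar& mp,
                               const Bounds& bb) {
  if (sp == SP_H) {
    if (mp.mut_gH && unif_rand() < mp.Pmut)
      gmax = mutate_value(gmax, 0.0, bb.gH_hi, mp.pnull, mp.splus, mp.sminus);
    if (mp.mut_affHR && unif_rand() < mp.Pmut)
      affR = mutate_value(affR, 0.0, bb.affHR_hi, mp.pnull, mp.splus,
                          mp.sminus);
  } else {
    if (mp.mut_gM && unif_rand() < mp.Pmut)
      gmax = mutate_value(gmax, 0.0, bb.gM_hi, mp.pnull, mp.splus, mp.sminus);
    if (mp.mut_affMR && unif_rand() < mp.Pmut)
      affR = mutate_value(affR, 0.0, bb.affMR_hi, mp.pnull, mp.splus,
                          mp.sminus);
    if (mp.mut_affMB && unif_rand() < mp.Pmut)
      affB = mutate_value(affB, 0.0, bb.affMB_hi, mp.pnull, mp.splus,
                          mp.sminus);
    if (mp.mut_fP && unif_rand() < mp.Pmut) {
      double sp_eff, sm_eff;
      epistatic_scales(fP, mp, sp_eff, sm_eff);
      fP = mutate_value(fP, 0.0, bb.fP_hi, mp.pnull, sp_eff, sm_eff);
    }
  }
}

// [[Rcpp::export]]
List mutate_cell_cpp(int species, double gmax, double affR, double affB,
                     double fP, List mut, List bounds) {
  MutPar mp = mutpar_from_list(mut);
  Bounds bb = bounds_from_list(bounds);
  double aB = NumericVector::is_na(affB) ? 0.0 : affB;
  double f = NumericVector::is_na(fP) ? 0.0 : fP;
  mutate_cell(species, gmax, affR, aB, f, mp, bb);
  return List::create(_["gmax"] = gmax, _["affR"] = affR,
                      _["affB"] = species == SP_M ? aB : affB,
                      _["fP"] = species == SP_M ? f : fP);
}

// Full Newborn-to-Adult maturation: repeated (chemistry, growth, death,
// division, mutation) steps from time 0 to T in increments of dtau.
// [[Rcpp::export]]
List mature_cpp(IntegerVector species, NumericVector L, NumericVector gmax,
                NumericVector affR, NumericVector affB, NumericVector fP,
                double R, double B, double P, double T, double dtau,
                List fixed, List mut, List bounds, double deltaH,
                double deltaM, double rtol = 1e-6, double atol = 1e-9) {
  ChemPar cp = chempar_from_list(fixed);
  MutPar mp = mutpar_from_list(mut);
  Bounds bb = bounds_from_list(bounds);

  int nsteps = (int)std::lround(T / dtau);
  if (std::fabs(nsteps * dtau - T) > 1e-8 * std::max(1.0, T))
    stop("maturation time T must be an integer multiple of dtau");

  size_t n = species.size();
  std::vector<int> c_sp(n);
  std::vector<double> c_L(n), c_g(n), c_aR(n), c_aB(n), c_fP(n);
  for (size_t i = 0; i < n; ++i) {
    c_sp[i] = species[i];
    c_L[i] = L[i];
    c_g[i] = gmax[i];
    c_aR[i] = affR[i];
    c_aB[i] = NumericVector::is_na(affB[i]) ? 0.0 : affB[i];
    c_fP[i] = NumericVector::is_na(fP[i]) ? 0.0 : fP[i];
  }

  double pH = deltaH * dtau, pM = deltaM * dtau;
  if (pH < 0.0 || pH > 1.0 || pM < 0.0 || pM > 1.0)
    stop("death probability per step must lie in [0, 1]");

  long deaths = 0, divisions = 0;
  std::vector<Grp> grps;
  std::vector<int> gi;
  std::map<std::array<double, 4>, int> gmap;

  for (int step = 0; step < nsteps; ++step) {
    n = c_sp.size();
    if (n == 0) break; // chemistry alone leaves R and B unchanged

    // --- phenotype groups (exact equality of growth-relevant parameters)
    grps.clear();
    gmap.clear();
    gi.resize(n);
    for (size_t i = 0; i < n; ++i) {
      std::array<double, 4> key = {(double)c_sp[i], c_g[i], c_aR[i], c_aB[i]};
      auto it = gmap.find(key);
      int k;
      if (it == gmap.end()) {
        k = (int)grps.size();
        gmap[key] = k;
        Grp g;
        g.species = c_sp[i];
        g.gmax = c_g[i];
        g.affR = c_aR[i];
        g.affB = c_aB[i];
        g.biomass = 0.0;
        g.integ = 0.0;
        grps.push_back(g);
      } else {
        k = it->second;
      }
      grps[k].biomass += c_L[i];
      gi[i] = k;
    }

    // --- chemicals + growth integrals with frozen biomasses
    chem_step_core(R, B, grps, dtau, cp, rtol, atol);

    // --- biomass growth and Product bookkeeping
    for (size_t i = 0; i < n; ++i) {
      double I = grps[gi[i]].integ;
      if (c_sp[i] == SP_H) {
        c_L[i] *= std::exp(I);
      } else {
        double f = c_fP[i];
        if (f >= 1.0) {
          P += c_L[i] * I; // analytic fP -> 1 limit: no biomass growth
        } else {
          double Ln = c_L[i] * std::exp((1.0 - f) * I);
          P += f / (1.0 - f) * (Ln - c_L[i]);
          c_L[i] = Ln;
        }
      }
    }

    // --- stochastic death (one uniform per cell, in order)
    size_t w = 0;
    for (size_t i = 0; i < n; ++i) {
      double p = (c_sp[i] == SP_H) ? pH : pM;
      double u = unif_rand();
      if (u >= p) {
        c_sp[w] = c_sp[i];
        c_L[w] = c_L[i];
        c_g[w] = c_g[i];
        c_aR[w] = c_aR[i];
        c_aB[w] = c_aB[i];
        c_fP[w] = c_fP[i];
        ++w;
      } else {
        ++deaths;
      }
    }
    c_sp.resize(w);
    c_L.resize(w);
    c_g.resize(w);
    c_aR.resize(w);
    c_aB.resize(w);
    c_fP.resize(w);
    n = w;

    // --- division (daughter inserted right after the mother) + mutation
    bool any_div = false;
    for (size_t i = 0; i < n; ++i)
      if (c_L[i] >= 2.0) {
        any_div = true;
        break;
      }
    if (any_div) {
      std::vector<int> d_sp;
      std::vector<double> d_L, d_g, d_aR, d_aB, d_fP;
      std::vector<size_t> newly; // indices (in new arrays) of divided cells
      d_sp.reserve(2 * n);
      d_L.reserve(2 * n);
      d_g.reserve(2 * n);
      d_aR.reserve(2 * n);
      d_aB.reserve(2 * n);
      d_fP.reserve(2 * n);
      for (size_t i = 0; i < n; ++i) {
        if (c_L[i] >= 2.0) {
          ++divisions;
          double half = c_L[i] / 2.0;
          for (int r = 0; r < 2; ++r) {
            newly.push_back(d_sp.size());
            d_sp.push_back(c_sp[i]);
            d_L.push_back(half);
            d_g.push_back(c_g[i]);
            d_aR.push_back(c_aR[i]);
            d_aB.push_back(c_aB[i]);
            d_fP.push_back(c_fP[i]);
          }
        } else {
          d_sp.push_back(c_sp[i]);
          d_L.push_back(c_L[i]);
          d_g.push_back(c_g[i]);
          d_aR.push_back(c_aR[i]);
          d_aB.push_back(c_aB[i]);
          d_fP.push_back(c_fP[i]);
        }
      }
      // one occurrence draw per mutable phenotype per divided cell,
      // whatever P_mut is, so that replay streams are scheme-independent
      for (size_t q = 0; q < newly.size(); ++q) {
        size_t i = newly[q];
        mutate_cell(d_sp[i], d_g[i], d_aR[i], d_aB[i], d_fP[i], mp, bb);
      }
      c_sp.swap(d_sp);
      c_L.swap(d_L);
      c_g.swap(d_g);
      c_aR.swap(d_aR);
      c_aB.swap(d_aB);
      c_fP.swap(d_fP);
    }
  }

  n = c_sp.size();
  IntegerVector o_sp(n);
  NumericVector o_L(n), o_g(n), o_aR(n), o_aB(n), o_fP(n);
  for (size_t i = 0; i < n; ++i) {
    o_sp[i] = c_sp[i];
    o_L[i] = c_L[i];
    o_g[i] = c_g[i];
    o_aR[i] = c_aR[i];
    if (c_sp[i] == SP_H) {
      o_aB[i] = NA_REAL;
      o_fP[i] = NA_REAL;
    } else {
      o_aB[i] = c_aB[i];
      o_fP[i] = c_fP[i];
    }
  }
  return List::create(_["species"] = o_sp, _["L"] = o_L, _["gmax"] = o_g,
                      _["affR"] = o_aR, _["affB"] = o_aB, _["fP"] = o_fP,
                      _["R"] = R, _["B"] = B, _["P"] = P,
                      _["extinct"] = (n == 0), _["deaths"] = (double)deaths,
                      _["divisions"] = (double)divisions);
}
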