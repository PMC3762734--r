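// Core numerics: TNNP 2004 (epicardial) human ventricular myocyte, passive
// RC fibroblast, single myocyte-fibroblast composite integration, and the
// 2D bilayer monodomain stepper with zero-/one-/two-sided couplings.
//
// All integration is forward Euler at a fixed dt (an exponential Rush-Larsen
// gate update is available behind a flag for single-cell work). The tissue
// stepper evaluates voltage-dependent rate/current factors through linear
// interpolation in precomputed tables; table spacing is chosen so the
// interpolation error is far below the discretisation error of the scheme.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------

struct TnnpParams {
  // physical constants
  double R, T, F, RTONF;
  // external concentrations (mM)
  double Ko, Cao, Nao;
  // intracellular volumes (um^3 in the model's unit system)
  double Vc, Vsr;
  // capacitance (uF); 0.185 uF = 185 pF total cellular capacitance
  double CAPACITANCE;
  // buffering / SR
  double Bufc, Kbufc, Bufsr, Kbufsr, taufca, taug, Vmaxup, Kup;
  double arel, brel, crel, Vleak;
  // maximal conductances / permeabilities (epicardial set)
  double GNa, GK1, Gto, GKr, GKs, pKNa, GCaL, knaca, KmNai, KmCa, ksat, n_naca;
  double knak, KmK, KmNa, GpCa, KpCa, GpK, GbNa, GbCa;
};

static TnnpParams params_from_list(const List& p) {
  TnnpParams q;
  q.R = as<double>(p["R"]);   q.T = as<double>(p["T"]);
  q.F = as<double>(p["F"]);   q.RTONF = q.R * q.T / q.F;
  q.Ko = as<double>(p["Ko"]); q.Cao = as<double>(p["Cao"]);
  q.Nao = as<double>(p["Nao"]);
  q.Vc = as<double>(p["Vc"]); q.Vsr = as<double>(p["Vsr"]);
  q.CAPACITANCE = as<double>(p["CAPACITANCE"]);
  q.Bufc = as<double>(p["Bufc"]);   q.Kbufc = as<double>(p["Kbufc"]);
  q.Bufsr = as<double>(p["Bufsr"]); q.Kbufsr = as<double>(p["Kbufsr"]);
  q.taufca = as<double>(p["taufca"]); q.taug = as<double>(p["taug"]);
  q.Vmaxup = as<double>(p["Vmaxup"]); q.Kup = as<double>(p["Kup"]);
  q.arel = as<double>(p["arel"]); q.brel = as<double>(p["brel"]);
  q.crel = as<double>(p["crel"]); q.Vleak = as<double>(p["Vleak"]);
  q.GNa = as<double>(p["GNa"]); q.GK1 = as<double>(p["GK1"]);
  q.Gto = as<double>(p["Gto"]); q.GKr = as<double>(p["GKr"]);
  q.GKs = as<double>(p["GKs"]); q.pKNa = as<double>(p["pKNa"]);
  q.GCaL = as<double>(p["GCaL"]); q.knaca = as<double>(p["knaca"]);
  q.KmNai = as<double>(p["KmNai"]); q.KmCa = as<double>(p["KmCa"]);
  q.ksat = as<double>(p["ksat"]); q.n_naca = as<double>(p["n_naca"]);
  q.knak = as<double>(p["knak"]); q.KmK = as<double>(p["KmK"]);
  q.KmNa = as<double>(p["KmNa"]); q.GpCa = as<double>(p["GpCa"]);
  q.KpCa = as<double>(p["KpCa"]); q.GpK = as<double>(p["GpK"]);
  q.GbNa = as<double>(p["GbNa"]); q.GbCa = as<double>(p["GbCa"]);
  return q;
}

// State layout (shared with the R side; order is frozen):
// 0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 fCa, 7 r, 8 s, 9 xr1, 10 xr2, 11 xs,
// 12 g, 13 Cai, 14 CaSR, 15 Nai, 16 Ki
#define NSTATE 17

struct Currents {
  double INa, ICaL, Ito, IKs, IKr, IK1, INaCa, INaK, IpCa, IpK, IbNa, IbCa;
  double Iion;
};

// Ionic currents, analytic form (pA/pF).
static inline Currents tnnp_currents(const double* s, const TnnpParams& p) {
  const double V = s[0], m = s[1], h = s[2], j = s[3], d = s[4], f = s[5],
    fCa = s[6], r = s[7], ss = s[8], xr1 = s[9], xr2 = s[10], xs = s[11],
    Cai = s[13], Nai = s[15], Ki = s[16];
  const double Ek  = p.RTONF * std::log(p.Ko / Ki);
  const double Ena = p.RTONF * std::log(p.Nao / Nai);
  const double Eks = p.RTONF * std::log((p.Ko + p.pKNa * p.Nao) /
                                        (Ki + p.pKNa * Nai));
  const double Eca = 0.5 * p.RTONF * std::log(p.Cao / Cai);

  Currents c;
  c.INa = p.GNa * m * m * m * h * j * (V - Ena);

  // L-type Ca current (GHK-type driving term); limit at V = 0 handled by
  // the exponential never being exactly 1 in double arithmetic except V==0.
  double vfort = 2.0 * V * p.F / (p.R * p.T);
  double ical_df;
  if (std::fabs(V) < 1e-9) {
    // series limit of 4VF^2/(RT) * (Cai e^x - 0.341 Cao)/(e^x - 1) at V->0
    ical_df = 2.0 * p.F * (Cai - 0.341 * p.Cao);
  } else {
    double e2 = std::exp(vfort);
    ical_df = 4.0 * V * p.F * p.F / (p.R * p.T) *
      (Cai * e2 - 0.341 * p.Cao) / (e2 - 1.0);
  }
  c.ICaL = p.GCaL * d * f * fCa * ical_df;

  c.Ito = p.Gto * r * ss * (V - Ek);
  c.IKr = p.GKr * std::sqrt(p.Ko / 5.4) * xr1 * xr2 * (V - Ek);
  c.IKs = p.GKs * xs * xs * (V - Eks);

  double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                std::exp(0.1 * (V - Ek - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - Ek)));
  c.IK1 = p.GK1 * std::sqrt(p.Ko / 5.4) * Ak1 / (Ak1 + Bk1) * (V - Ek);

  double vf = V * p.F / (p.R * p.T);
  double eg  = std::exp(p.n_naca * vf);
  double eg1 = std::exp((p.n_naca - 1.0) * vf);
  c.INaCa = p.knaca *
    (1.0 / (p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao)) *
    (1.0 / (p.KmCa + p.Cao)) * (1.0 / (1.0 + p.ksat * eg1)) *
    (eg * Nai * Nai * Nai * p.Cao - eg1 * p.Nao * p.Nao * p.Nao * Cai * 2.5);

  double rec_nak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vf) +
                          0.0353 * std::exp(-vf));
  c.INaK = p.knak * (p.Ko / (p.Ko + p.KmK)) * (Nai / (Nai + p.KmNa)) * rec_nak;

  c.IpCa = p.GpCa * Cai / (p.KpCa + Cai);
  c.IpK  = p.GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IbNa = p.GbNa * (V - Ena);
  c.IbCa = p.GbCa * (V - Eca);

  c.Iion = c.INa + c.ICaL + c.Ito + c.IKs + c.IKr + c.IK1 + c.INaCa +
    c.INaK + c.IpCa + c.IpK + c.IbNa + c.IbCa;
  return c;
}

struct GateRates {
  // steady-state value and time constant for the 11 V-gated variables
  double m_inf, tau_m, h_inf, tau_h, j_inf, tau_j, d_inf, tau_d, f_inf, tau_f,
    r_inf, tau_r, s_inf, tau_s, xr1_inf, tau_xr1, xr2_inf, tau_xr2,
    xs_inf, tau_xs;
};

static inline GateRates tnnp_gate_rates(double V) {
  GateRates g;
  double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
  g.tau_m = AM * BM;
  double mi = 1.0 / (1.0 + std::exp((-56.86 - V) / 9.03));
  g.m_inf = mi * mi;

  double hi = 1.0 / (1.0 + std::exp((V + 71.55) / 7.43));
  g.h_inf = hi * hi;
  double AH, BH;
  if (V >= -40.0) {
    AH = 0.0;
    BH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
    BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  g.tau_h = 1.0 / (AH + BH);

  g.j_inf = g.h_inf;
  double AJ, BJ;
  if (V >= -40.0) {
    AJ = 0.0;
    BJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    AJ = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    BJ = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g.tau_j = 1.0 / (AJ + BJ);

  g.xr1_inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  g.tau_xr1 = axr1 * bxr1;

  g.xr2_inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  g.tau_xr2 = axr2 * bxr2;

  g.xs_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double axs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
  g.tau_xs = axs * bxs;

  // epicardial transient-outward gates
  g.r_inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  g.tau_r = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  g.s_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  g.tau_s = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

  g.d_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
  double Ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double Bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double Cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  g.tau_d = Ad * Bd + Cd;

  g.f_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  g.tau_f = 1125.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
            165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  return g;
}

static inline double fca_inf_of(double Cai) {
  double rr = Cai / 0.000325;
  double r2 = rr * rr, r4 = r2 * r2;
  double alpha = 1.0 / (1.0 + r4 * r4);
  double beta = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
  double gama = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
  return (alpha + beta + gama + 0.23) / 1.46;
}

static inline double g_inf_of(double Cai) {
  double rr = Cai / 0.00035;
  if (Cai <= 0.00035) {
    double r2 = rr * rr;
    return 1.0 / (1.0 + r2 * r2 * r2);
  }
  double r2 = rr * rr, r4 = r2 * r2, r8 = r4 * r4;
  return 1.0 / (1.0 + r8 * r8);
}

// One forward-Euler step of gates + concentrations, given the currents and
// the already-updated membrane potential Vnew. Istim in pA/pF participates
// in the K+ balance with the model's sign convention.
static inline void tnnp_update_state(double* s, const Currents& c,
                                     const TnnpParams& p, double dt,
                                     double Istim, bool rush_larsen) {
  const double V = s[0];
  GateRates g = tnnp_gate_rates(V);
  if (rush_larsen) {
    s[1] = g.m_inf - (g.m_inf - s[1]) * std::exp(-dt / g.tau_m);
    s[2] = g.h_inf - (g.h_inf - s[2]) * std::exp(-dt / g.tau_h);
    s[3] = g.j_inf - (g.j_inf - s[3]) * std::exp(-dt / g.tau_j);
    s[4] = g.d_inf - (g.d_inf - s[4]) * std::exp(-dt / g.tau_d);
    s[5] = g.f_inf - (g.f_inf - s[5]) * std::exp(-dt / g.tau_f);
    s[7] = g.r_inf - (g.r_inf - s[7]) * std::exp(-dt / g.tau_r);
    s[8] = g.s_inf - (g.s_inf - s[8]) * std::exp(-dt / g.tau_s);
    s[9] = g.xr1_inf - (g.xr1_inf - s[9]) * std::exp(-dt / g.tau_xr1);
    s[10] = g.xr2_inf - (g.xr2_inf - s[10]) * std::exp(-dt / g.tau_xr2);
    s[11] = g.xs_inf - (g.xs_inf - s[11]) * std::exp(-dt / g.tau_xs);
  } else {
    s[1] += dt * (g.m_inf - s[1]) / g.tau_m;
    s[2] += dt * (g.h_inf - s[2]) / g.tau_h;
    s[3] += dt * (g.j_inf - s[3]) / g.tau_j;
    s[4] += dt * (g.d_inf - s[4]) / g.tau_d;
    s[5] += dt * (g.f_inf - s[5]) / g.tau_f;
    s[7] += dt * (g.r_inf - s[7]) / g.tau_r;
    s[8] += dt * (g.s_inf - s[8]) / g.tau_s;
    s[9] += dt * (g.xr1_inf - s[9]) / g.tau_xr1;
    s[10] += dt * (g.xr2_inf - s[10]) / g.tau_xr2;
    s[11] += dt * (g.xs_inf - s[11]) / g.tau_xs;
  }

  // Ca-dependent gates with their voltage lock (no relaxation toward a larger
  // steady state while depolarised)
  double Cai = s[13];
  double fci = fca_inf_of(Cai);
  if (!(fci > s[6] && V > -60.0)) s[6] += dt * (fci - s[6]) / p.taufca;
  double gi = g_inf_of(Cai);
  if (!(gi > s[12] && V > -60.0)) s[12] += dt * (gi - s[12]) / p.taug;
  if (s[6] > 1.0) s[6] = 1.0;
  if (s[12] > 1.0) s[12] = 1.0;

  // Ca dynamics with instantaneous-buffer algebra (the model's scheme)
  double CaSR = s[14];
  double Ileak = p.Vleak * (CaSR - Cai);
  double Iup = p.Vmaxup / (1.0 + (p.Kup * p.Kup) / (Cai * Cai));
  double Irel = (p.arel * CaSR * CaSR / (p.brel * p.brel + CaSR * CaSR) +
                 p.crel) * s[4] * s[12];
  double inverseVcF2 = 1.0 / (2.0 * p.Vc * p.F);
  double CaCurrent = -(c.ICaL + c.IbCa + c.IpCa - 2.0 * c.INaCa) *
    inverseVcF2 * p.CAPACITANCE;
  double CaSRCurrent = Iup - Irel - Ileak;

  double CaCSQN = p.Bufsr * CaSR / (CaSR + p.Kbufsr);
  double dCaSR = dt * (p.Vc / p.Vsr) * CaSRCurrent;
  double bjsr = p.Bufsr - CaCSQN - dCaSR - CaSR + p.Kbufsr;
  double cjsr = p.Kbufsr * (CaCSQN + dCaSR + CaSR);
  s[14] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  double CaBuf = p.Bufc * Cai / (Cai + p.Kbufc);
  double dCai = dt * (CaCurrent - CaSRCurrent);
  double bc = p.Bufc - CaBuf - dCai - Cai + p.Kbufc;
  double cc = p.Kbufc * (CaBuf + dCai + Cai);
  s[13] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  double inverseVcF = 1.0 / (p.Vc * p.F);
  s[15] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                 inverseVcF * p.CAPACITANCE);
  s[16] += dt * (-(Istim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK +
                   c.IpK) * inverseVcF * p.CAPACITANCE);
}

// ---------------------------------------------------------------------------
// Exported: single evaluation of the current breakdown (used by R wrappers
// and for per-current traces)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_currents")]]
NumericVector cpp_currents(NumericVector state, List pars) {
  TnnpParams p = params_from_list(pars);
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Currents c = tnnp_currents(REAL(state), p);
  NumericVector out = NumericVector::create(
    _["I_Na"] = c.INa, _["I_CaL"] = c.ICaL, _["I_to"] = c.Ito,
    _["I_Ks"] = c.IKs, _["I_Kr"] = c.IKr, _["I_K1"] = c.IK1,
    _["I_NaCa"] = c.INaCa, _["I_NaK"] = c.INaK, _["I_pCa"] = c.IpCa,
    _["I_pK"] = c.IpK, _["I_bNa"] = c.IbNa, _["I_bCa"] = c.IbCa,
    _["I_ion"] = c.Iion);
  return out;
}

// ---------------------------------------------------------------------------
// Exported: single-cell MF composite run
// ---------------------------------------------------------------------------

static inline double stim_at(const NumericMatrix& stim, double t) {
  double a = 0.0;
  for (int k = 0; k < stim.nrow(); ++k) {
    if (t >= stim(k, 0) && t < stim(k, 0) + stim(k, 1)) a += stim(k, 2);
  }
  return a;
}

// [[Rcpp::export(name = ".cpp_run_composite")]]
List cpp_run_composite(NumericVector state0, NumericVector vf0, List pars,
                       double Cf, double Gf, double Ef, double gj, double Cm,
                       NumericMatrix stim, double dt, double t_end,
                       int sample_every, bool record_currents,
                       bool rush_larsen) {
  TnnpParams p = params_from_list(pars);
  if (state0.size() != NSTATE) stop("state must have %d entries", NSTATE);
  std::vector<double> s(REAL(state0), REAL(state0) + NSTATE);
  std::vector<double> vf(vf0.begin(), vf0.end());
  const int nf = (int)vf.size();
  const long nsteps = (long)std::lround(t_end / dt);
  const long nsamp = nsteps / sample_every + 1;

  NumericVector t_out(nsamp), vm_out(nsamp), vf_out(nsamp), igap_out(nsamp);
  NumericMatrix cur_out = record_currents ? NumericMatrix(nsamp, 13)
                                          : NumericMatrix(1, 1);

  long isamp = 0;
  for (long it = 0; it <= nsteps; ++it) {
    double t = it * dt;
    Currents c = tnnp_currents(s.data(), p);
    // gap current: sum over junctions, pA, positive when leaving the myocyte
    double igap = 0.0;
    for (int k = 0; k < nf; ++k) igap += gj * (s[0] - vf[k]);

    if (it % sample_every == 0) {
      t_out[isamp] = t; vm_out[isamp] = s[0];
      vf_out[isamp] = nf > 0 ? vf[0] : NA_REAL;
      igap_out[isamp] = igap;
      if (record_currents) {
        cur_out(isamp, 0) = c.INa;  cur_out(isamp, 1) = c.ICaL;
        cur_out(isamp, 2) = c.Ito;  cur_out(isamp, 3) = c.IKs;
        cur_out(isamp, 4) = c.IKr;  cur_out(isamp, 5) = c.IK1;
        cur_out(isamp, 6) = c.INaCa; cur_out(isamp, 7) = c.INaK;
        cur_out(isamp, 8) = c.IpCa; cur_out(isamp, 9) = c.IpK;
        cur_out(isamp, 10) = c.IbNa; cur_out(isamp, 11) = c.IbCa;
        cur_out(isamp, 12) = c.Iion;
      }
      ++isamp;
    }
    if (it == nsteps) break;

    double Istim = stim_at(stim, t);
    double vold = s[0];
    s[0] += dt * (-(c.Iion + Istim) - igap / Cm);
    for (int k = 0; k < nf; ++k) {
      vf[k] += dt * (-Gf * (vf[k] - Ef) + gj * (vold - vf[k])) / Cf;
    }
    // gates/concentrations advance from the pre-step V
    double keep = s[0]; s[0] = vold;
    tnnp_update_state(s.data(), c, p, dt, Istim, rush_larsen);
    s[0] = keep;

    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0) {
      stop("unstable integration: |V_m| = %g mV at t = %g ms", s[0], t + dt);
    }
  }

  List out = List::create(
    _["t"] = t_out, _["V_m"] = vm_out, _["V_f"] = vf_out,
    _["I_gap"] = igap_out,
    _["state"] = NumericVector(s.begin(), s.end()),
    _["V_f_final"] = NumericVector(vf.begin(), vf.end()));
  if (record_currents) out["currents"] = cur_out;
  return out;
}

// ---------------------------------------------------------------------------
// Lookup tables for the tissue stepper
// ---------------------------------------------------------------------------

// columns of the V-table
enum {
  C_MINF, C_RM, C_HINF, C_RH, C_JINF, C_RJ, C_DINF, C_RD, C_FINF, C_RF,
  C_RINF, C_RR, C_SINF, C_RS, C_XR1INF, C_RXR1, C_XR2INF, C_RXR2,
  C_XSINF, C_RXS, C_CAL1, C_CAL2, C_NACA1, C_NACA2, C_NAK, C_PK, NCOLV
};

struct Lut {
  // V-dependent factors
  double v0, iv;            // origin and 1/step
  int nv;
  std::vector<double> tv;   // nv rows x NCOLV, row-major
  // IK1 factor on u = V - Ek (includes the (V-Ek) driving term)
  double u0, iu; int nu; std::vector<double> tk1;
  // log tables for reversal potentials
  double k0, ik; int nk; std::vector<double> tlogk;   // log(Ki), Ki in [80,180]
  double na0, ina; int nna; std::vector<double> tlogna; // log(Nai)
  double ks0, iks; int nks; std::vector<double> tlogks; // log(Ki+pKNa*Nai)
  double c0, ic; int nc; std::vector<double> tca;       // per Cai: logCai, fca_inf, g_inf
};

static void build_lut(Lut& L, const TnnpParams& p, double dt) {
  const double vmin = -110.0, vmax = 80.0, dv = 0.05;
  L.v0 = vmin; L.iv = 1.0 / dv; L.nv = (int)std::lround((vmax - vmin) / dv) + 1;
  L.tv.assign((size_t)L.nv * NCOLV, 0.0);
  for (int i = 0; i < L.nv; ++i) {
    double V = vmin + i * dv;
    GateRates g = tnnp_gate_rates(V);
    double* row = &L.tv[(size_t)i * NCOLV];
    // gate columns: steady state and the exponential (Rush-Larsen)
    // per-step decay factor exp(-dt/tau)
    row[C_MINF] = g.m_inf; row[C_RM] = std::exp(-dt / g.tau_m);
    row[C_HINF] = g.h_inf; row[C_RH] = std::exp(-dt / g.tau_h);
    row[C_JINF] = g.j_inf; row[C_RJ] = std::exp(-dt / g.tau_j);
    row[C_DINF] = g.d_inf; row[C_RD] = std::exp(-dt / g.tau_d);
    row[C_FINF] = g.f_inf; row[C_RF] = std::exp(-dt / g.tau_f);
    row[C_RINF] = g.r_inf; row[C_RR] = std::exp(-dt / g.tau_r);
    row[C_SINF] = g.s_inf; row[C_RS] = std::exp(-dt / g.tau_s);
    row[C_XR1INF] = g.xr1_inf; row[C_RXR1] = std::exp(-dt / g.tau_xr1);
    row[C_XR2INF] = g.xr2_inf; row[C_RXR2] = std::exp(-dt / g.tau_xr2);
    row[C_XSINF] = g.xs_inf; row[C_RXS] = std::exp(-dt / g.tau_xs);

    // ICaL = d f fCa (CAL1 * Cai - CAL2)
    if (std::fabs(V) < 1e-9) {
      row[C_CAL1] = p.GCaL * 2.0 * p.F;
      row[C_CAL2] = p.GCaL * 2.0 * p.F * 0.341 * p.Cao;
    } else {
      double e2 = std::exp(2.0 * V * p.F / (p.R * p.T));
      double A = p.GCaL * 4.0 * V * p.F * p.F / (p.R * p.T) / (e2 - 1.0);
      row[C_CAL1] = A * e2;
      row[C_CAL2] = A * 0.341 * p.Cao;
    }

    // INaCa = NACA1 * Nai^3 - NACA2 * Cai
    double vf = V * p.F / (p.R * p.T);
    double eg = std::exp(p.n_naca * vf), eg1 = std::exp((p.n_naca - 1.0) * vf);
    double pref = p.knaca /
      ((p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao) *
       (p.KmCa + p.Cao) * (1.0 + p.ksat * eg1));
    row[C_NACA1] = pref * eg * p.Cao;
    row[C_NACA2] = pref * eg1 * p.Nao * p.Nao * p.Nao * 2.5;

    row[C_NAK] = p.knak * (p.Ko / (p.Ko + p.KmK)) /
      (1.0 + 0.1245 * std::exp(-0.1 * vf) + 0.0353 * std::exp(-vf));
    row[C_PK] = p.GpK / (1.0 + std::exp((25.0 - V) / 5.98));
  }

  // IK1 table on u = V - Ek, IK1 = GK1 sqrt(Ko/5.4) rec(u) * u
  const double umin = -120.0, umax = 220.0, du = 0.05;
  L.u0 = umin; L.iu = 1.0 / du; L.nu = (int)std::lround((umax - umin) / du) + 1;
  L.tk1.resize(L.nu);
  double gk1 = p.GK1 * std::sqrt(p.Ko / 5.4);
  for (int i = 0; i < L.nu; ++i) {
    double u = umin + i * du;
    double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
    double Bk1 = (3.0 * std::exp(0.0002 * (u + 100.0)) +
                  std::exp(0.1 * (u - 10.0))) / (1.0 + std::exp(-0.5 * u));
    L.tk1[i] = gk1 * Ak1 / (Ak1 + Bk1) * u;
  }

  const double kmin = 80.0, kmax = 180.0, dk = 0.002;
  L.k0 = kmin; L.ik = 1.0 / dk; L.nk = (int)std::lround((kmax - kmin) / dk) + 1;
  L.tlogk.resize(L.nk);
  L.tlogks.resize(L.nk);
  for (int i = 0; i < L.nk; ++i) L.tlogk[i] = std::log(kmin + i * dk);
  // log(Ki + pKNa*Nai) reuses the same grid on x = Ki + pKNa*Nai
  for (int i = 0; i < L.nk; ++i) L.tlogks[i] = std::log(kmin + i * dk);
  L.ks0 = kmin; L.iks = L.ik; L.nks = L.nk;

  const double namin = 2.0, namax = 40.0, dna = 0.001;
  L.na0 = namin; L.ina = 1.0 / dna;
  L.nna = (int)std::lround((namax - namin) / dna) + 1;
  L.tlogna.resize(L.nna);
  for (int i = 0; i < L.nna; ++i) L.tlogna[i] = std::log(namin + i * dna);

  const double cmin = 1e-6, cmax = 0.02, dc = 1e-6;
  L.c0 = cmin; L.ic = 1.0 / dc; L.nc = (int)std::lround((cmax - cmin) / dc) + 1;
  L.tca.assign((size_t)L.nc * 3, 0.0);
  for (int i = 0; i < L.nc; ++i) {
    double cai = cmin + i * dc;
    L.tca[(size_t)i * 3] = std::log(cai);
    L.tca[(size_t)i * 3 + 1] = fca_inf_of(cai);
    L.tca[(size_t)i * 3 + 2] = g_inf_of(cai);
  }
  (void)dt;
}

static inline double lin1(const std::vector<double>& t, double x0, double ix,
                          int n, double x) {
  double u = (x - x0) * ix;
  if (u <= 0.0) return t[0];
  if (u >= n - 1) return t[n - 1];
  int i = (int)u; double w = u - i;
  return t[i] + (t[i + 1] - t[i]) * w;
}

// ---------------------------------------------------------------------------
// Exported: 2D bilayer tissue run
// ---------------------------------------------------------------------------

// grid state passed as an nx*ny x NSTATE matrix (column per variable,
// nodes in column-major (i fastest) order to match R matrices)
//
// coupling/control scalars packed in a named list to keep the signature sane.

// [[Rcpp::export(name = ".cpp_run_tissue")]]
List cpp_run_tissue(NumericMatrix state, NumericVector vf_in,
                    LogicalVector mask_in, NumericVector ggap_in,
                    List pars, List opts, List stimuli,
                    double t0, double t_end) {
  TnnpParams p = params_from_list(pars);
  const int nx = as<int>(opts["nx"]), ny = as<int>(opts["ny"]);
  const double dx_cm = as<double>(opts["dx_mm"]) * 0.1;
  const double D = as<double>(opts["D"]);
  const double dt = as<double>(opts["dt"]);
  const double Cm = as<double>(opts["Cm"]);
  const double Cf = as<double>(opts["Cf"]), Gf = as<double>(opts["Gf"]),
    Ef = as<double>(opts["Ef"]);
  const double Gff = as<double>(opts["Gff"]);
  const double Gmf = as<double>(opts["Gmf"]), Gfm = as<double>(opts["Gfm"]);
  const double Gx = Gmf + Gfm;   // combined cross-layer pair conductance
  const bool pure_diffusion = as<bool>(opts["pure_diffusion"]);
  const int sample_every = as<int>(opts["sample_every"]);
  const IntegerVector probes = opts["probes"];       // 0-based node ids
  const NumericVector snap_times = opts["snap_times"]; // absolute ms
  const bool snap_vf = as<bool>(opts["snap_vf"]);
  const bool snap_ina = as<bool>(opts["snap_ina"]);
  // the stored sodium-current field is the peak |I_Na| per node over the
  // `ina_hold` ms preceding each snapshot: the instantaneous activation
  // line can be narrower than one lattice cell, the short hold paints it
  // as a contiguous front line
  const double ina_hold = as<double>(opts["ina_hold"]);
  // optional schedule of D multipliers: matrix (t_from, factor) rows
  const NumericMatrix dsched = opts["d_schedule"];

  const int nn = nx * ny;
  if (state.nrow() != nn || state.ncol() != NSTATE)
    stop("state matrix must be (nx*ny) x %d", NSTATE);

  // working copies (SoA)
  std::vector<std::vector<double> > S(NSTATE);
  for (int v = 0; v < NSTATE; ++v) {
    S[v].assign(&state(0, v), &state(0, v) + nn);
  }
  std::vector<double> vf(vf_in.begin(), vf_in.end());
  std::vector<char> mask(nn);
  for (int i = 0; i < nn; ++i) mask[i] = mask_in[i] ? 1 : 0;
  std::vector<double> ggap(ggap_in.begin(), ggap_in.end());
  const bool any_fib = std::find(mask.begin(), mask.end(), 1) != mask.end();

  std::vector<double> vm_new(nn), vf_new(any_fib ? nn : 0);
  std::vector<double> ina_max(snap_ina ? nn : 0, 0.0);

  Lut L; build_lut(L, p, dt);

  // stimuli: list of (start, dur, amp, idx (0-based))
  const int nstim = stimuli.size();
  std::vector<double> st_start(nstim), st_dur(nstim), st_amp(nstim);
  std::vector<IntegerVector> st_idx(nstim);
  for (int k = 0; k < nstim; ++k) {
    List e = stimuli[k];
    st_start[k] = as<double>(e["start"]);
    st_dur[k] = as<double>(e["dur"]);
    st_amp[k] = as<double>(e["amp"]);
    st_idx[k] = as<IntegerVector>(e["idx"]);
  }
  std::vector<double> istim(nn, 0.0);

  const long nsteps = (long)std::lround((t_end - t0) / dt);
  const long nsamp = nsteps / sample_every + 1;
  const int nprobe = probes.size();
  NumericMatrix probe_vm(nsamp, nprobe);
  NumericMatrix probe_vf(any_fib && nprobe > 0 ? nsamp : 1,
                         any_fib ? nprobe : 1);
  NumericVector probe_t(nsamp);

  const int nsnap = snap_times.size();
  List snaps_vm(nsnap), snaps_vf(nsnap), snaps_ina(nsnap);
  NumericVector snap_t_out(nsnap);
  int isnap = 0;

  const double rtonf = p.RTONF;
  const double logKo = std::log(p.Ko);
  const double logNao = std::log(p.Nao);
  const double logCao = std::log(p.Cao);
  const double logKs_num = std::log(p.Ko + p.pKNa * p.Nao);
  const double inverseVcF2 = 1.0 / (2.0 * p.Vc * p.F);
  const double inverseVcF = 1.0 / (p.Vc * p.F);

  long isamp = 0;
  for (long it = 0; it <= nsteps; ++it) {
    double t = t0 + it * dt;

    // D(t) from the schedule (used by the spiral-initiation protocol)
    double Dnow = D;
    for (int k = 0; k < dsched.nrow(); ++k) {
      if (t >= dsched(k, 0)) Dnow = D * dsched(k, 1);
    }
    const double dcoef = Dnow / (dx_cm * dx_cm);

    // sampling
    if (it % sample_every == 0) {
      probe_t[isamp] = t;
      for (int q = 0; q < nprobe; ++q) probe_vm(isamp, q) = S[0][probes[q]];
      if (any_fib)
        for (int q = 0; q < nprobe; ++q) probe_vf(isamp, q) = vf[probes[q]];
      ++isamp;
    }
    while (isnap < nsnap && t >= snap_times[isnap] - 0.5 * dt) {
      NumericMatrix mvm(nx, ny);
      std::memcpy(REAL(mvm), S[0].data(), sizeof(double) * nn);
      snaps_vm[isnap] = mvm;
      if (snap_vf && any_fib) {
        NumericMatrix mvf(nx, ny);
        std::memcpy(REAL(mvf), vf.data(), sizeof(double) * nn);
        snaps_vf[isnap] = mvf;
      }
      if (snap_ina) {
        NumericMatrix mina(nx, ny);
        std::memcpy(REAL(mina), ina_max.data(), sizeof(double) * nn);
        snaps_ina[isnap] = mina;
        std::fill(ina_max.begin(), ina_max.end(), 0.0);
      }
      snap_t_out[isnap] = t;
      ++isnap;
    }
    if (it == nsteps) break;

    const bool ina_acc = snap_ina && isnap < nsnap &&
      t >= snap_times[isnap] - ina_hold - 0.5 * dt;

    // stimulus field for this step
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int k = 0; k < nstim; ++k) {
      if (t >= st_start[k] && t < st_start[k] + st_dur[k]) {
        const IntegerVector& ix = st_idx[k];
        for (int q = 0; q < ix.size(); ++q) istim[ix[q]] += st_amp[k];
      }
    }

    // myocyte layer
    for (int jy = 0; jy < ny; ++jy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int id = jy * nx + ix;
        const double V = S[0][id];

        // diffusion: sum over in-grid neighbours (no-flux)
        double lap = 0.0;
        if (ix > 0) lap += S[0][id - 1] - V;
        if (ix < nx - 1) lap += S[0][id + 1] - V;
        if (jy > 0) lap += S[0][id - nx] - V;
        if (jy < ny - 1) lap += S[0][id + nx] - V;

        if (pure_diffusion) {
          vm_new[id] = V + dt * dcoef * lap;
          continue;
        }

        // table row interpolation
        double u = (V - L.v0) * L.iv;
        if (u < 0.0) u = 0.0;
        if (u > L.nv - 1.000001) u = L.nv - 1.000001;
        const int iv = (int)u;
        const double w = u - iv;
        const double* r0 = &L.tv[(size_t)iv * NCOLV];
        const double* r1 = r0 + NCOLV;
        double row[NCOLV];
        for (int cidx = 0; cidx < NCOLV; ++cidx)
          row[cidx] = r0[cidx] + (r1[cidx] - r0[cidx]) * w;

        const double Cai = S[13][id], Nai = S[15][id], Ki = S[16][id];
        const double logKi = lin1(L.tlogk, L.k0, L.ik, L.nk, Ki);
        const double Ek = rtonf * (logKo - logKi);
        const double logNai = lin1(L.tlogna, L.na0, L.ina, L.nna, Nai);
        const double Ena = rtonf * (logNao - logNai);
        const double logKsd = lin1(L.tlogks, L.ks0, L.iks, L.nks,
                                   Ki + p.pKNa * Nai);
        const double Eks = rtonf * (logKs_num - logKsd);

        // Cai sub-table
        double uc = (Cai - L.c0) * L.ic;
        if (uc < 0.0) uc = 0.0;
        if (uc > L.nc - 1.000001) uc = L.nc - 1.000001;
        const int ic = (int)uc; const double wc = uc - ic;
        const double* c0p = &L.tca[(size_t)ic * 3];
        const double logCai = c0p[0] + (c0p[3] - c0p[0]) * wc;
        const double fci = c0p[1] + (c0p[4] - c0p[1]) * wc;
        const double gii = c0p[2] + (c0p[5] - c0p[2]) * wc;
        const double Eca = 0.5 * rtonf * (logCao - logCai);

        Currents c;
        const double m = S[1][id], h = S[2][id], jj = S[3][id];
        c.INa = p.GNa * m * m * m * h * jj * (V - Ena);
        c.ICaL = S[4][id] * S[5][id] * S[6][id] *
          (row[C_CAL1] * Cai - row[C_CAL2]);
        c.Ito = p.Gto * S[7][id] * S[8][id] * (V - Ek);
        c.IKr = p.GKr * std::sqrt(p.Ko / 5.4) * S[9][id] * S[10][id] * (V - Ek);
        c.IKs = p.GKs * S[11][id] * S[11][id] * (V - Eks);
        c.IK1 = lin1(L.tk1, L.u0, L.iu, L.nu, V - Ek);
        c.INaCa = row[C_NACA1] * Nai * Nai * Nai - row[C_NACA2] * Cai;
        c.INaK = row[C_NAK] * Nai / (Nai + p.KmNa);
        c.IpCa = p.GpCa * Cai / (p.KpCa + Cai);
        c.IpK = row[C_PK] * (V - Ek);
        c.IbNa = p.GbNa * (V - Ena);
        c.IbCa = p.GbCa * (V - Eca);
        c.Iion = c.INa + c.ICaL + c.Ito + c.IKs + c.IKr + c.IK1 + c.INaCa +
          c.INaK + c.IpCa + c.IpK + c.IbNa + c.IbCa;

        if (ina_acc) {
          double aIna = std::fabs(c.INa);
          if (aIna > ina_max[id]) ina_max[id] = aIna;
        }

        // couplings to the fibroblast layer (pA -> pA/pF via Cm)
        double icup = 0.0;
        if (any_fib) {
          if (mask[id]) icup += ggap[id] * (V - vf[id]);
          if (Gx > 0.0) {
            if (ix > 0 && mask[id - 1]) icup += Gx * (V - vf[id - 1]);
            if (ix < nx - 1 && mask[id + 1]) icup += Gx * (V - vf[id + 1]);
            if (jy > 0 && mask[id - nx]) icup += Gx * (V - vf[id - nx]);
            if (jy < ny - 1 && mask[id + nx]) icup += Gx * (V - vf[id + nx]);
          }
        }

        vm_new[id] = V + dt * (-(c.Iion + istim[id]) + dcoef * lap -
                               icup / Cm);

        // gate updates (exponential / Rush-Larsen, table factors)
        S[1][id] = row[C_MINF] - (row[C_MINF] - m) * row[C_RM];
        S[2][id] = row[C_HINF] - (row[C_HINF] - h) * row[C_RH];
        S[3][id] = row[C_JINF] - (row[C_JINF] - jj) * row[C_RJ];
        S[4][id] = row[C_DINF] - (row[C_DINF] - S[4][id]) * row[C_RD];
        S[5][id] = row[C_FINF] - (row[C_FINF] - S[5][id]) * row[C_RF];
        S[7][id] = row[C_RINF] - (row[C_RINF] - S[7][id]) * row[C_RR];
        S[8][id] = row[C_SINF] - (row[C_SINF] - S[8][id]) * row[C_RS];
        S[9][id] = row[C_XR1INF] - (row[C_XR1INF] - S[9][id]) * row[C_RXR1];
        S[10][id] = row[C_XR2INF] - (row[C_XR2INF] - S[10][id]) * row[C_RXR2];
        S[11][id] = row[C_XSINF] - (row[C_XSINF] - S[11][id]) * row[C_RXS];
        if (!(fci > S[6][id] && V > -60.0))
          S[6][id] += dt * (fci - S[6][id]) / p.taufca;
        if (!(gii > S[12][id] && V > -60.0))
          S[12][id] += dt * (gii - S[12][id]) / p.taug;
        if (S[6][id] > 1.0) S[6][id] = 1.0;
        if (S[12][id] > 1.0) S[12][id] = 1.0;

        // concentrations
        double CaSR = S[14][id];
        double Ileak = p.Vleak * (CaSR - Cai);
        double Iup = p.Vmaxup / (1.0 + (p.Kup * p.Kup) / (Cai * Cai));
        double Irel = (p.arel * CaSR * CaSR /
                       (p.brel * p.brel + CaSR * CaSR) + p.crel) *
          S[4][id] * S[12][id];
        double CaCurrent = -(c.ICaL + c.IbCa + c.IpCa - 2.0 * c.INaCa) *
          inverseVcF2 * p.CAPACITANCE;
        double CaSRCurrent = Iup - Irel - Ileak;
        double CaCSQN = p.Bufsr * CaSR / (CaSR + p.Kbufsr);
        double dCaSR = dt * (p.Vc / p.Vsr) * CaSRCurrent;
        double bjsr = p.Bufsr - CaCSQN - dCaSR - CaSR + p.Kbufsr;
        double cjsr = p.Kbufsr * (CaCSQN + dCaSR + CaSR);
        S[14][id] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
        double CaBuf = p.Bufc * Cai / (Cai + p.Kbufc);
        double dCai = dt * (CaCurrent - CaSRCurrent);
        double bc = p.Bufc - CaBuf - dCai - Cai + p.Kbufc;
        double cc2 = p.Kbufc * (CaBuf + dCai + Cai);
        S[13][id] = (std::sqrt(bc * bc + 4.0 * cc2) - bc) / 2.0;
        S[15][id] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                           inverseVcF * p.CAPACITANCE);
        S[16][id] += dt * (-(istim[id] + c.IK1 + c.Ito + c.IKr + c.IKs -
                             2.0 * c.INaK + c.IpK) *
                           inverseVcF * p.CAPACITANCE);
      }
    }

    // fibroblast layer (uses pre-step myocyte potentials: exchanges are
    // evaluated at the same time level on both sides)
    if (any_fib && !pure_diffusion) {
      for (int jy = 0; jy < ny; ++jy) {
        for (int ix = 0; ix < nx; ++ix) {
          const int id = jy * nx + ix;
          if (!mask[id]) continue;
          const double W = vf[id];
          double cur = -Gf * (W - Ef) + ggap[id] * (S[0][id] - W);
          if (Gff > 0.0) {
            if (ix > 0 && mask[id - 1]) cur += Gff * (vf[id - 1] - W);
            if (ix < nx - 1 && mask[id + 1]) cur += Gff * (vf[id + 1] - W);
            if (jy > 0 && mask[id - nx]) cur += Gff * (vf[id - nx] - W);
            if (jy < ny - 1 && mask[id + nx]) cur += Gff * (vf[id + nx] - W);
          }
          if (Gx > 0.0) {
            if (ix > 0) cur += Gx * (S[0][id - 1] - W);
            if (ix < nx - 1) cur += Gx * (S[0][id + 1] - W);
            if (jy > 0) cur += Gx * (S[0][id - nx] - W);
            if (jy < ny - 1) cur += Gx * (S[0][id + nx] - W);
          }
          vf_new[id] = W + dt * cur / Cf;
        }
      }
      for (int i = 0; i < nn; ++i) if (mask[i]) vf[i] = vf_new[i];
    }

    std::swap(S[0], vm_new);

    if (it % 500 == 0) {
      // divergence sentinel; strong stimuli legitimately push V above
      // +200 mV for a few ms, so only truly runaway values abort
      double v = S[0][nn / 2];
      if (!std::isfinite(v) || std::fabs(v) > 1e5)
        stop("unstable integration: V_m = %g mV at node %d, t = %g ms",
             v, nn / 2, t + dt);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix state_out(nn, NSTATE);
  for (int v = 0; v < NSTATE; ++v)
    std::memcpy(&state_out(0, v), S[v].data(), sizeof(double) * nn);

  return List::create(
    _["probe_t"] = probe_t, _["probe_vm"] = probe_vm,
    _["probe_vf"] = probe_vf,
    _["snap_t"] = snap_t_out, _["snap_vm"] = snaps_vm,
    _["snap_vf"] = snaps_vf, _["snap_ina"] = snaps_ina,
    _["state"] = state_out,
    _["vf"] = NumericVector(vf.begin(), vf.end()),
    _["t_end"] = t0 + nsteps * dt);
}
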