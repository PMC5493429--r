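// Courtemanche-lineage human atrial myocyte model (21 states), with either
// its native I_Kur gating or the voltage-dependent-conductance I_Kur
// formulation swapped in.  Currents are densities in pA/pF; concentrations
// in mM; time in ms.

#include "models.h"

namespace ctm {

const double F = 96.4867;          // C/mmol
const double RTF = 26.712832;      // mV at 310 K
const double FoRT = 1.0 / RTF;
const double Cm = 100.0;           // pF
const double Vi = 13668.0;         // um^3
const double Vup = 1109.52;
const double Vrel = 96.48;
const double Ko = 5.4, Nao = 140.0, Cao = 1.8;

const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
const double gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375;
const double gbCa = 0.00113, gbNa = 0.0006744375;
const double INaKmax = 0.59933874, INaCamax = 1600.0, IpCamax = 0.275;
const double Iupmax = 0.005, caupmax = 15.0, krel = 30.0;
const double KQ10 = 3.0;
const double sigma_nak = 1.00091;  // (exp(Nao/67.3)-1)/7

const double cmdnmax = 0.05, trpnmax = 0.07, csqnmax = 10.0;
const double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;

// state indices
enum { S_V = 0, S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI, S_XR, S_XS,
       S_D, S_F, S_FCA, S_U, S_VG, S_W, S_NAI, S_KI, S_CAI, S_CAUP,
       S_CAREL, N_STATE };

// LUT tables: per gate (inf, exp(-dt/tau)) then auxiliary voltage factors
enum { L_MI = 0, L_ME, L_HI, L_HE, L_JI, L_JE, L_OAI, L_OAE, L_OII, L_OIE,
       L_UAI, L_UAE, L_UII, L_UIE, L_XRI, L_XRE, L_XSI, L_XSE, L_DI, L_DE,
       L_FI, L_FE, L_WI, L_WE, L_IK1R, L_IKRR, L_GKURV, L_FNAK,
       L_NCXE1, L_NCXE2, N_LUT };

static void default_state(double* y) {
  y[S_V] = -81.18; y[S_M] = 0.002908; y[S_H] = 0.9649; y[S_J] = 0.9775;
  y[S_OA] = 0.03043; y[S_OI] = 0.9992; y[S_UA] = 0.004966; y[S_UI] = 0.9986;
  y[S_XR] = 3.296e-5; y[S_XS] = 0.01869; y[S_D] = 1.367e-4; y[S_F] = 0.9996;
  y[S_FCA] = 0.7755; y[S_U] = 0.0; y[S_VG] = 1.0; y[S_W] = 0.9992;
  y[S_NAI] = 11.17; y[S_KI] = 139.0; y[S_CAI] = 1.013e-4;
  y[S_CAUP] = 1.488; y[S_CAREL] = 1.488;
}

// steady-state / tau of the new I_Kur formulation (Q10-corrected)
static double new_ikur_ainf(double v, const double* p) {
  double a = 1.0 / (1.0 + std::exp((v - p[CP_ACT_VH1]) / p[CP_ACT_K1]));
  if ((int)p[CP_ACT_N] == 2)
    a *= 1.0 / (1.0 + std::exp((v - p[CP_ACT_VH2]) / p[CP_ACT_K2]));
  return a;
}
static double new_ikur_taua(double v) {
  double b1 = 45.67 / (1.0 + std::exp((v + 11.23) / 11.53)) + 4.27;
  double b2 = 0.26 / (1.0 + std::exp((v + 35.87) / -3.88)) + 0.29;
  return b1 * b2 / 3.52;
}
static double new_ikur_iinf(double v, const double* p) {
  return p[CP_INACT_AMP] /
           (1.0 + std::exp((v - p[CP_INACT_VH]) / p[CP_INACT_K])) +
         p[CP_INACT_FLOOR];
}
static double new_ikur_taui(double v) {
  return (2328.0 / (1.0 + std::exp((v - 9.44) / 3.58)) + 1739.14) / 3.52;
}
static double new_ikur_g(double v) {
  // nS per cell conductance shape; used as density via /Cm
  return 0.64 * (4.51 + 1.90 / (1.0 + std::exp((v - 20.52) / -8.27)));
}

static void build_lut(Lut& lut, const double* p, double dt) {
  lut.init(-120.0, 90.0, 0.02, N_LUT);
  const bool newkur = (int)p[CP_IKUR_MODE] == 1;
  for (int i = 0; i <= lut.n; ++i) {
    double v = lut.vmin + i * lut.dv;
    double* r = lut.row(i);

    // INa gates (Luo-Rudy style)
    double am = (std::fabs(v + 47.13) < 1e-9)
                    ? 3.2
                    : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
    double bm = 0.08 * std::exp(-v / 11.0);
    r[L_MI] = am / (am + bm);
    r[L_ME] = std::exp(-dt * (am + bm));
    double ah, bh, aj, bj;
    if (v >= -40.0) {
      ah = 0.0;
      bh = 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.3 * std::exp(-2.535e-7 * v) /
           (1.0 + std::exp(-0.1 * (v + 32.0)));
    } else {
      ah = 0.135 * std::exp(-(v + 80.0) / 6.8);
      bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
      aj = (-1.2714e5 * std::exp(0.2444 * v) -
            3.474e-5 * std::exp(-0.04391 * v)) *
           (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
      bj = 0.1212 * std::exp(-0.01052 * v) /
           (1.0 + std::exp(-0.1378 * (v + 40.14)));
    }
    r[L_HI] = ah / (ah + bh); r[L_HE] = std::exp(-dt * (ah + bh));
    r[L_JI] = aj / (aj + bj); r[L_JE] = std::exp(-dt * (aj + bj));

    // Ito gates
    double aoa = 0.65 / (std::exp(-(v + 10.0) / 8.5) +
                         std::exp(-(v - 30.0) / 59.0));
    double boa = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
    r[L_OAI] = 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54));
    r[L_OAE] = std::exp(-dt * (aoa + boa) * KQ10);
    double aoi = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
    double boi = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
    r[L_OII] = 1.0 / (1.0 + std::exp((v + 43.1) / 5.3));
    r[L_OIE] = std::exp(-dt * (aoi + boi) * KQ10);

    // I_Kur gates: native kinetics with (possibly variant-shifted)
    // steady-state Boltzmanns, or the new formulation
    if (!newkur) {
      double aua = 0.65 / (std::exp(-(v + 10.0) / 8.5) +
                           std::exp(-(v - 30.0) / 59.0));
      double bua = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
      r[L_UAI] = 1.0 / (1.0 + std::exp((v - p[CP_ACT_VH1]) / p[CP_ACT_K1]));
      r[L_UAE] = std::exp(-dt * (aua + bua) * KQ10);
      double aui = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
      double bui = std::exp((v - 158.0) / 16.0);
      r[L_UII] = new_ikur_iinf(v, p);
      r[L_UIE] = std::exp(-dt * (aui + bui) * KQ10);
      r[L_GKURV] = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
    } else {
      r[L_UAI] = new_ikur_ainf(v, p);
      r[L_UAE] = std::exp(-dt / new_ikur_taua(v));
      r[L_UII] = new_ikur_iinf(v, p);
      r[L_UIE] = std::exp(-dt / new_ikur_taui(v));
      r[L_GKURV] = new_ikur_g(v) / Cm;  // nS -> nS/pF with Cm = 100 pF
    }

    // IKr / IKs
    double axr = safe_ratio(0.0003 * (v + 14.1),
                            1.0 - std::exp(-(v + 14.1) / 5.0));
    double bxr = safe_ratio(7.3898e-5 * (v - 3.3328),
                            std::exp((v - 3.3328) / 5.1237) - 1.0);
    r[L_XRI] = 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5));
    r[L_XRE] = std::exp(-dt * (axr + bxr));
    double vxs = v - p[CP_XSSHIFT];  // beta-adrenergic shift
    double axs = safe_ratio(4e-5 * (vxs - 19.9),
                            1.0 - std::exp(-(vxs - 19.9) / 17.0));
    double bxs = safe_ratio(3.5e-5 * (vxs - 19.9),
                            std::exp((vxs - 19.9) / 9.0) - 1.0);
    r[L_XSI] = 1.0 / std::sqrt(1.0 + std::exp(-(vxs - 19.9) / 12.7));
    r[L_XSE] = std::exp(-dt * 2.0 * (axs + bxs));  // tau_xs = 0.5/(a+b)

    // ICaL voltage gates (d shifted under beta-adrenergic stimulation)
    double vd = v - p[CP_DSHIFT];
    double dd = 1.0 - std::exp(-(vd + 10.0) / 6.24);
    double taud = (std::fabs(vd + 10.0) < 1e-9)
                      ? 4.579 / (1.0 + std::exp(-(vd + 10.0) / 6.24))
                      : dd / (0.035 * (vd + 10.0) * (1.0 + std::exp(-(vd + 10.0) / 6.24)));
    r[L_DI] = 1.0 / (1.0 + std::exp(-(vd + 10.0) / 8.0));
    r[L_DE] = std::exp(-dt / taud);
    double tauf = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 *
                                           (v + 10.0) * (v + 10.0)) + 0.02);
    r[L_FI] = 1.0 / (1.0 + std::exp((v + 28.0) / 6.9));
    r[L_FE] = std::exp(-dt / tauf);

    // SR release w gate
    double x = v - 7.9;
    double tauw = (std::fabs(x) < 1e-6)
                      ? 6.0 * 0.2 / 1.3
                      : 6.0 * (1.0 - std::exp(-x / 5.0)) /
                            ((1.0 + 0.3 * std::exp(-x / 5.0)) * x);
    r[L_WI] = 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0));
    r[L_WE] = std::exp(-dt / tauw);

    // auxiliary voltage factors
    r[L_IK1R] = 1.0 / (1.0 + std::exp(0.07 * (v + 80.0)));
    r[L_IKRR] = 1.0 / (1.0 + std::exp((v + 15.0) / 22.4));
    r[L_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v * FoRT) +
                       0.0365 * sigma_nak * std::exp(-v * FoRT));
    r[L_NCXE1] = std::exp(0.35 * v * FoRT);
    r[L_NCXE2] = std::exp(-0.65 * v * FoRT);
  }
}

static void step(double* y, const double* p, const Lut& lut, double dt,
                 double i_ext) {
  double L[N_LUT];
  const double v = y[S_V];
  lut.lookup(v, L);

  const double Nai = y[S_NAI], Ki = y[S_KI], Cai = y[S_CAI];
  const double ENa = RTF * std::log(Nao / Nai);
  const double EK = RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  // currents (pA/pF)
  const double m = y[S_M], h = y[S_H], j = y[S_J];
  const double ina = p[CP_GNA] * gNa * m * m * m * h * j * (v - ENa);
  const double ik1 = p[CP_GK1] * gK1 * (v - EK) * L[L_IK1R];
  const double oa = y[S_OA];
  const double ito = p[CP_GTO] * gto * oa * oa * oa * y[S_OI] * (v - EK);
  const double ua = y[S_UA], ui = y[S_UI];
  const bool newkur = (int)p[CP_IKUR_MODE] == 1;
  const double ikur = p[CP_GKUR] * L[L_GKURV] *
                      (newkur ? ua : ua * ua * ua) * ui * (v - EK);
  const double ikr = p[CP_GKR] * gKr * y[S_XR] * (v - EK) * L[L_IKRR];
  const double xs = y[S_XS];
  const double iks = p[CP_GKS] * gKs * xs * xs * (v - EK);
  const double ical = p[CP_GCAL] * gCaL * y[S_D] * y[S_F] * y[S_FCA] *
                      (v - 65.0);
  const double ipca = IpCamax * Cai / (0.0005 + Cai);
  const double inak = p[CP_GNAK] * INaKmax * L[L_FNAK] * Ko /
                      ((1.0 + std::pow(10.0 / Nai, 1.5)) * (Ko + 1.5));
  const double Nai3 = Nai * Nai * Nai;
  const double incx = p[CP_GNCX] * INaCamax *
                      (L[L_NCXE1] * Nai3 * Cao -
                       L[L_NCXE2] * Nao * Nao * Nao * Cai) /
                      ((87.5 * 87.5 * 87.5 + Nao * Nao * Nao) *
                       (1.38 + Cao) * (1.0 + 0.1 * L[L_NCXE2]));
  const double ibna = gbNa * (v - ENa);
  const double ibca = gbCa * (v - ECa);

  // SR fluxes (mM/ms)
  const double u = y[S_U], vg = y[S_VG], w = y[S_W];
  const double Carel = y[S_CAREL], Caup = y[S_CAUP];
  const double irel = krel * u * u * vg * w * (Carel - Cai);
  const double itr = (Caup - Carel) / 180.0;
  const double iup = p[CP_GUP] * Iupmax /
                     (1.0 + p[CP_KUPF] * 0.00092 / Cai);
  const double iupleak = p[CP_GUP] * Iupmax * Caup / caupmax;

  // Ca-release gating driven by Fn (flux units per the original model;
  // currents converted to pA via Cm)
  const double fn = 1e3 * (1e-15 * Vrel * irel -
                           1e-15 / (2.0 * F) *
                               (0.5 * ical * Cm - 0.2 * incx * Cm));
  const double uinf = 1.0 / (1.0 + std::exp(-(fn - 3.4175e-13) / 13.67e-16));
  const double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(fn - 6.835e-14) / 13.67e-16));
  const double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(fn - 3.4175e-13) / 13.67e-16));

  // gate updates (Rush-Larsen)
  y[S_M] = rl_step(m, L[L_MI], L[L_ME]);
  y[S_H] = rl_step(h, L[L_HI], L[L_HE]);
  y[S_J] = rl_step(j, L[L_JI], L[L_JE]);
  y[S_OA] = rl_step(oa, L[L_OAI], L[L_OAE]);
  y[S_OI] = rl_step(y[S_OI], L[L_OII], L[L_OIE]);
  y[S_UA] = rl_step(ua, L[L_UAI], L[L_UAE]);
  y[S_UI] = rl_step(ui, L[L_UII], L[L_UIE]);
  y[S_XR] = rl_step(y[S_XR], L[L_XRI], L[L_XRE]);
  y[S_XS] = rl_step(xs, L[L_XSI], L[L_XSE]);
  y[S_D] = rl_step(y[S_D], L[L_DI], L[L_DE]);
  y[S_F] = rl_step(y[S_F], L[L_FI], L[L_FE]);
  y[S_FCA] = rl_step(y[S_FCA], 1.0 / (1.0 + Cai / 0.00035),
                     std::exp(-dt / 2.0));
  y[S_U] = rl_step(u, uinf, std::exp(-dt / 8.0));
  y[S_VG] = rl_step(vg, vinf, std::exp(-dt / tauv));
  y[S_W] = rl_step(w, L[L_WI], L[L_WE]);

  // concentrations (forward Euler)
  const double cfac = Cm / (F * Vi);
  y[S_NAI] += dt * (-(3.0 * inak + 3.0 * incx + ibna + ina) * cfac);
  y[S_KI] += dt * ((2.0 * inak - ik1 - ito - ikur - ikr - iks) * cfac);
  const double b1 = (2.0 * incx - ipca - ical - ibca) * 0.5 * cfac +
                    (Vup * (iupleak - iup) + irel * Vrel) / Vi;
  const double b2 = 1.0 + trpnmax * KmTrpn / ((Cai + KmTrpn) * (Cai + KmTrpn)) +
                    cmdnmax * KmCmdn / ((Cai + KmCmdn) * (Cai + KmCmdn));
  y[S_CAI] += dt * b1 / b2;
  y[S_CAUP] += dt * (iup - iupleak - itr * Vrel / Vup);
  y[S_CAREL] += dt * (itr - irel) /
                (1.0 + csqnmax * KmCsqn / ((Carel + KmCsqn) * (Carel + KmCsqn)));

  const double iion = ina + ik1 + ito + ikur + ikr + iks + ical + ipca +
                      inak + incx + ibna + ibca;
  y[S_V] += dt * (-iion + i_ext);
}

}  // namespace ctm

const CellModel& ctm_model() {
  static CellModel m = {ctm::N_STATE, ctm::N_LUT, ctm::default_state,
                        ctm::build_lut, ctm::step};
  return m;
}
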