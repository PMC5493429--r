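// Grandi-lineage human atrial myocyte model (39 states): junctional /
// subsarcolemmal / cytosolic compartments, GHK L-type Ca current, RyR
// release with luminal regulation, explicit Na and Ca buffering, native
// chronic-AF and 1 uM isoprenaline (beta-adrenergic) parameter sets.
// Currents are densities in pA/pF; concentrations in mM; time in ms.

#include "models.h"

namespace grandi {

const double Frdy = 96485.0;       // C/mol
const double FoRT = 0.0374358835;  // 1/mV at 310 K
const double Cmem = 1.1e-10;       // F
const double Qpow = 0.0;           // (T - 310)/10

const double Ko = 5.4, Nao = 140.0, Cao = 1.8, Cli = 15.0, Clo = 150.0;
const double Ki_fixed = 120.0;     // bulk K+ held constant
const double Mgi = 1.0;
const double pNaK = 0.01833;

// geometry
const double Vcell = 3.30105e-11;  // L  (pi * 10.25^2 * 100 um^3)
const double Vmyo = 0.65 * Vcell, Vsr = 0.035 * Vcell;
const double Vsl = 0.02 * Vcell, Vjunc = 0.000539 * Vcell;
const double J_ca_juncsl = 1.0 / 1.2134e12, J_ca_slmyo = 1.0 / 2.68510e11;
const double J_na_juncsl = 1.0 / (1.6382e12 / 3.0 * 100.0);
const double J_na_slmyo = 1.0 / (1.8308e10 / 3.0 * 100.0);
const double Fjunc = 0.11, Fsl = 0.89;
const double Fjunc_CaL = 0.9, Fsl_CaL = 0.1;

// fixed conductances / transport maxima
const double GNa = 23.0, GNaB = 0.597e-3, IbarNaK = 1.26;
const double KmKo = 1.5;
const double gkp = 0.002;
const double GClCa = 0.0548, GClB = 9e-3, KdClCa = 0.1;
const double IbarNCX = 3.15;
const double KmCai = 3.59e-3, KmCao = 1.3, KmNai = 12.29, KmNao = 87.5;
const double ksat = 0.27, nu = 0.35, Kdact = 0.384e-3;
const double IbarSLCaP = 0.0471, KmPCa = 0.5e-3;
const double GCaB = 6.0643e-4;
const double Vmax_SRCaP = 5.3114e-3, Kmr = 1.7, hillSRCaP = 1.787;
const double ks = 25.0, kom = 0.06, kiCa = 0.5, kim = 0.005;
const double ec50SR = 0.45, MaxSR = 15.0, MinSR = 1.0;

// buffering
const double Bmax_Naj = 7.561, Bmax_Nasl = 1.65;
const double koff_na = 1e-3, kon_na = 1e-4;
const double Bmax_TnClow = 70e-3, kon_tncl = 32.7;
const double Bmax_TnChigh = 140e-3;
const double koff_tnchca = 0.032e-3, kon_tnchca = 2.37;
const double koff_tnchmg = 3.33e-3, kon_tnchmg = 3e-3;
const double Bmax_CaM = 24e-3, koff_cam = 238e-3, kon_cam = 34.0;
const double Bmax_myosin = 140e-3;
const double koff_myoca = 0.46e-3, kon_myoca = 13.8;
const double koff_myomg = 0.057e-3, kon_myomg = 0.0157;
const double Bmax_SR = 19.0 * 0.9e-3, koff_sr = 60e-3, kon_sr = 100.0;
const double koff_sll = 1300e-3, kon_sll = 100.0;
const double koff_slh = 30e-3, kon_slh = 100.0;
const double koff_csqn = 65.0, kon_csqn = 100.0;
const double Bmax_SLlowsl = 37.4e-3 * Vmyo / Vsl;
const double Bmax_SLlowj = 4.6e-3 * Vmyo / Vjunc * 0.1;
const double Bmax_SLhighsl = 13.4e-3 * Vmyo / Vsl;
const double Bmax_SLhighj = 1.65e-3 * Vmyo / Vjunc * 0.1;
const double Bmax_Csqn = 140e-3 * Vmyo / Vsr;

enum { S_V = 0, S_M, S_H, S_J, S_D, S_F, S_FCABJ, S_FCABSL,
       S_XTOF, S_YTOF, S_XKR, S_XKS, S_XKUR, S_YKUR,
       S_RYRR, S_RYRO, S_RYRI,
       S_NABJ, S_NABSL,
       S_TNCL, S_TNCHC, S_TNCHM, S_CAM, S_MYOC, S_MYOM, S_SRB,
       S_SLLJ, S_SLLSL, S_SLHJ, S_SLHSL, S_CSQNB,
       S_CASR, S_NAJ, S_NASL, S_NAI, S_KI, S_CAJ, S_CASL, S_CAI,
       N_STATE };

enum { L_MI = 0, L_ME, L_HI, L_HE, L_JI, L_JE, L_DI, L_DE, L_FI, L_FE,
       L_XTOFI, L_XTOFE, L_YTOFI, L_YTOFE, L_XKURI, L_XKURE,
       L_YKURI, L_YKURE, L_XKRI, L_XKRE, L_XKSI, L_XKSE,
       L_RKR, L_KP, L_FNAK, L_NCXE1, L_NCXE2,
       L_GHCA_A, L_GHCA_B, L_GHK_A, L_GHK_B, L_GHNA_A, L_GHNA_B,
       N_LUT };

// resting state obtained by equilibrating the quiescent model; close to the
// published resting conditions of this model lineage
static void default_state(double* y) {
  y[S_V] = -73.8; y[S_M] = 0.0; y[S_H] = 1.0; y[S_J] = 1.0;
  y[S_D] = 0.0; y[S_F] = 1.0; y[S_FCABJ] = 0.025; y[S_FCABSL] = 0.015;
  y[S_XTOF] = 0.0; y[S_YTOF] = 1.0; y[S_XKR] = 0.0; y[S_XKS] = 0.0;
  y[S_XKUR] = 0.0; y[S_YKUR] = 1.0;
  y[S_RYRR] = 1.0; y[S_RYRO] = 0.0; y[S_RYRI] = 0.0;
  y[S_NABJ] = 3.5; y[S_NABSL] = 0.8;
  y[S_TNCL] = 0.009; y[S_TNCHC] = 0.118; y[S_TNCHM] = 0.01;
  y[S_CAM] = 3e-4; y[S_MYOC] = 1.9e-3; y[S_MYOM] = 0.135;
  y[S_SRB] = 2.2e-3;
  y[S_SLLJ] = 0.01; y[S_SLLSL] = 0.01; y[S_SLHJ] = 0.07; y[S_SLHSL] = 0.07;
  y[S_CSQNB] = 1.2;
  y[S_CASR] = 0.5; y[S_NAJ] = 9.14; y[S_NASL] = 9.14; y[S_NAI] = 9.14;
  y[S_KI] = Ki_fixed; y[S_CAJ] = 1.7e-4; y[S_CASL] = 1.1e-4;
  y[S_CAI] = 9e-5;
}

static void build_lut(Lut& lut, const double* p, double dt) {
  lut.init(-120.0, 90.0, 0.02, N_LUT);
  const double ISO = p[GP_ISO];
  for (int i = 0; i <= lut.n; ++i) {
    double v = lut.vmin + i * lut.dv;
    double* r = lut.row(i);

    // INa (Luo-Rudy style kinetics, squared steady states)
    double mss = 1.0 / (1.0 + std::exp(-(56.86 + v) / 9.03));
    mss *= mss;
    double taum = 0.1292 * std::exp(-std::pow((v + 45.79) / 15.54, 2)) +
                  0.06487 * std::exp(-std::pow((v - 4.823) / 51.12, 2));
    r[L_MI] = mss; r[L_ME] = std::exp(-dt / taum);
    double ah = (v >= -40.0) ? 0.0 : 0.057 * std::exp(-(v + 80.0) / 6.8);
    double bh = (v >= -40.0)
                    ? 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)))
                    : 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
    double hss = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
    hss *= hss;
    r[L_HI] = hss; r[L_HE] = std::exp(-dt * (ah + bh));
    double aj = (v >= -40.0)
                    ? 0.0
                    : (-2.5428e4 * std::exp(0.2444 * v) -
                       6.948e-6 * std::exp(-0.04391 * v)) *
                          (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    double bj = (v >= -40.0)
                    ? 0.6 * std::exp(0.057 * v) /
                          (1.0 + std::exp(-0.1 * (v + 32.0)))
                    : 0.02424 * std::exp(-0.01052 * v) /
                          (1.0 + std::exp(-0.1378 * (v + 40.14)));
    r[L_JI] = hss;  // jss = hss in this formulation
    r[L_JE] = std::exp(-dt * (aj + bj));

    // ICaL voltage gates (beta-adrenergic stimulation shifts activation)
    double vd = v + 3.0 * ISO + 9.0;
    double dss = 1.0 / (1.0 + std::exp(-vd / 6.0));
    double taud = (std::fabs(vd) < 1e-9)
                      ? dss * (1.0 / 6.0) / 0.035
                      : dss * (1.0 - std::exp(-vd / 6.0)) / (0.035 * vd);
    r[L_DI] = dss; r[L_DE] = std::exp(-dt / taud);
    double fss = 1.0 / (1.0 + std::exp((v + 30.0) / 7.0)) +
                 0.2 / (1.0 + std::exp((50.0 - v) / 20.0));
    double tauf = 1.0 / (0.0197 * std::exp(-std::pow(0.0337 * (v + 25.0), 2)) +
                         0.02);
    r[L_FI] = fss; r[L_FE] = std::exp(-dt / tauf);

    // Ito (fast component; atrial reformulation)
    double xtoss = 1.0 / (1.0 + std::exp(-(v + 1.0) / 11.0));
    double tauxtof = 3.5 * std::exp(-std::pow(v / 30.0, 2)) + 1.5;
    double ytoss = 1.0 / (1.0 + std::exp((v + 40.5) / 11.5));
    double tauytof =
        25.635 * std::exp(-std::pow((v + 52.45) / 15.8827, 2)) + 24.14;
    r[L_XTOFI] = xtoss; r[L_XTOFE] = std::exp(-dt / tauxtof);
    r[L_YTOFI] = ytoss; r[L_YTOFE] = std::exp(-dt / tauytof);

    // IKur gates: native kinetics, steady states possibly variant-shifted
    double xkss = 1.0 / (1.0 + std::exp((v - p[GP_KUR_AVH]) / p[GP_KUR_AK]));
    double tauxkur = 9.0 / (1.0 + std::exp((v + 5.0) / 12.0)) + 0.5;
    double ykss = (1.0 - p[GP_KUR_MA]) /
                      (1.0 + std::exp((v - p[GP_KUR_IVH]) / p[GP_KUR_IK])) +
                  p[GP_KUR_MA];
    double tauykur = 590.0 / (1.0 + std::exp((v + 60.0) / 10.0)) + 3050.0;
    r[L_XKURI] = xkss; r[L_XKURE] = std::exp(-dt / tauxkur);
    r[L_YKURI] = ykss; r[L_YKURE] = std::exp(-dt / tauykur);

    // IKr
    double xrss = 1.0 / (1.0 + std::exp(-(v + 10.0) / 5.0));
    double tauxr = 550.0 / (1.0 + std::exp((-22.0 - v) / 9.0)) * 6.0 /
                       (1.0 + std::exp((v + 11.0) / 9.0)) +
                   230.0 / (1.0 + std::exp((v + 40.0) / 20.0));
    r[L_XKRI] = xrss; r[L_XKRE] = std::exp(-dt / tauxr);
    r[L_RKR] = 1.0 / (1.0 + std::exp((v + 74.0) / 24.0));

    // IKs (beta-adrenergic stimulation shifts activation)
    double vxs = v + 40.0 * ISO;
    double xsss = 1.0 / (1.0 + std::exp(-(vxs + 3.8) / 14.25));
    double tauxs = 990.1 / (1.0 + std::exp(-(vxs + 2.436) / 14.12));
    r[L_XKSI] = xsss; r[L_XKSE] = std::exp(-dt / tauxs);

    r[L_KP] = 1.0 / (1.0 + std::exp(7.488 - v / 5.98));
    double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    r[L_FNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v * FoRT) +
                       0.0365 * sigma * std::exp(-v * FoRT));
    r[L_NCXE1] = std::exp(nu * v * FoRT);
    r[L_NCXE2] = std::exp((nu - 1.0) * v * FoRT);

    // GHK driving-force factors, I = A(v)*C_in - B(v)
    double e2 = std::exp(2.0 * v * FoRT);
    double de2 = (std::fabs(e2 - 1.0) < 1e-9) ? 1e-9 : (e2 - 1.0);
    double fca4 = 4.0 * v * Frdy * FoRT / de2;
    if (std::fabs(v) < 1e-9) fca4 = 4.0 * Frdy / (2.0 * FoRT) * FoRT;  // limit
    r[L_GHCA_A] = fca4 * 0.341 * e2;
    r[L_GHCA_B] = fca4 * 0.341 * Cao;
    double e1 = std::exp(v * FoRT);
    double de1 = (std::fabs(e1 - 1.0) < 1e-9) ? 1e-9 : (e1 - 1.0);
    double fmono = v * Frdy * FoRT / de1;
    if (std::fabs(v) < 1e-9) fmono = Frdy;
    r[L_GHK_A] = fmono * 0.75 * e1;
    r[L_GHK_B] = fmono * 0.75 * Ko;
    r[L_GHNA_A] = fmono * 0.75 * e1;
    r[L_GHNA_B] = fmono * 0.75 * Nao;
  }
}

static void step(double* y, const double* p, const Lut& lut, double dt,
                 double i_ext) {
  double L[N_LUT];
  const double v = y[S_V];
  lut.lookup(v, L);

  const double AF = p[GP_AF], ISO = p[GP_ISO];
  const double Naj = y[S_NAJ], Nasl = y[S_NASL], Nai = y[S_NAI];
  const double Caj = y[S_CAJ], Casl = y[S_CASL], Cai = y[S_CAI];
  const double Casr = y[S_CASR], Ki = y[S_KI];

  const double ena_junc = (1.0 / FoRT) * std::log(Nao / Naj);
  const double ena_sl = (1.0 / FoRT) * std::log(Nao / Nasl);
  const double ek = (1.0 / FoRT) * std::log(Ko / Ki);
  const double eca_junc = (0.5 / FoRT) * std::log(Cao / Caj);
  const double eca_sl = (0.5 / FoRT) * std::log(Cao / Casl);
  const double ecl = (1.0 / FoRT) * std::log(Cli / Clo);

  // INa
  const double m = y[S_M], h = y[S_H], j = y[S_J];
  const double gna = p[GP_GNA] * GNa * (1.0 - 0.1 * AF);
  const double I_Na_junc = Fjunc * gna * m * m * m * h * j * (v - ena_junc);
  const double I_Na_sl = Fsl * gna * m * m * m * h * j * (v - ena_sl);

  const double I_nabk_junc = Fjunc * GNaB * (v - ena_junc);
  const double I_nabk_sl = Fsl * GNaB * (v - ena_sl);

  // INaK (beta-adrenergic stimulation increases Na affinity)
  const double KmNaip = 11.0 * (1.0 - 0.25 * ISO);
  const double km4j = std::pow(KmNaip / Naj, 4.0);
  const double km4sl = std::pow(KmNaip / Nasl, 4.0);
  const double I_nak_junc = p[GP_GNAK] * Fjunc * IbarNaK * L[L_FNAK] * Ko /
                            ((1.0 + km4j) * (Ko + KmKo));
  const double I_nak_sl = p[GP_GNAK] * Fsl * IbarNaK * L[L_FNAK] * Ko /
                          ((1.0 + km4sl) * (Ko + KmKo));
  const double I_nak = I_nak_junc + I_nak_sl;

  // K currents
  const double gkr = p[GP_GKR] * 0.035 * std::sqrt(Ko / 5.4);
  const double I_kr = gkr * y[S_XKR] * L[L_RKR] * (v - ek);
  const double eks = (1.0 / FoRT) *
                     std::log((Ko + pNaK * Nao) / (Ki + pNaK * Nai));
  const double gks = p[GP_GKS] * (1.0 + AF + 2.0 * ISO) * 0.0035;
  const double xks = y[S_XKS];
  const double I_ks = gks * xks * xks * (v - eks);
  const double I_kp = gkp * L[L_KP] * (v - ek);
  const double gto = p[GP_GTO] * (1.0 - 0.7 * AF) * 0.165;
  const double I_to = gto * y[S_XTOF] * y[S_YTOF] * (v - ek);
  const double gkur = p[GP_GKUR] * (1.0 - 0.5 * AF) * (1.0 + 2.0 * ISO) * 0.045;
  const double I_kur = gkur * y[S_XKUR] * y[S_YKUR] * (v - ek);
  const double aki = 1.02 / (1.0 + std::exp(0.2385 * (v - ek - 59.215)));
  const double bki = (0.49124 * std::exp(0.08032 * (v + 5.476 - ek)) +
                      std::exp(0.06175 * (v - ek - 594.31))) /
                     (1.0 + std::exp(-0.5143 * (v - ek + 4.753)));
  const double I_ki = p[GP_GK1] * (1.0 + AF) * 0.0525 *
                      std::sqrt(Ko / 5.4) * aki / (aki + bki) * (v - ek);

  // Cl currents
  const double I_ClCa = Fjunc * GClCa / (1.0 + KdClCa / Caj) * (v - ecl) +
                        Fsl * GClCa / (1.0 + KdClCa / Casl) * (v - ecl);
  const double I_Clbk = GClB * (v - ecl);

  // ICaL (GHK; beta-adrenergic stimulation increases permeability)
  const double pscale = p[GP_GCAL] * (1.0 + 0.5 * ISO) * (1.0 - 0.5 * AF);
  const double pCa = pscale * 2.7e-4, pK = pscale * 1.35e-7,
               pNa = pscale * 0.75e-8;
  const double d = y[S_D], f = y[S_F];
  const double fcaj = y[S_FCABJ], fcasl = y[S_FCABSL];
  const double ibarca_j = pCa * (L[L_GHCA_A] * Caj - L[L_GHCA_B]);
  const double ibarca_sl = pCa * (L[L_GHCA_A] * Casl - L[L_GHCA_B]);
  const double ibark = pK * (L[L_GHK_A] * Ki - L[L_GHK_B]);
  const double ibarna_j = pNa * (L[L_GHNA_A] * Naj - L[L_GHNA_B]);
  const double ibarna_sl = pNa * (L[L_GHNA_A] * Nasl - L[L_GHNA_B]);
  const double I_Ca_junc = Fjunc_CaL * ibarca_j * d * f * (1.0 - fcaj) * 0.45;
  const double I_Ca_sl = Fsl_CaL * ibarca_sl * d * f * (1.0 - fcasl) * 0.45;
  const double I_CaK = ibark * d * f *
                       (Fjunc_CaL * (1.0 - fcaj) + Fsl_CaL * (1.0 - fcasl)) *
                       0.45;
  const double I_CaNa_junc = Fjunc_CaL * ibarna_j * d * f * (1.0 - fcaj) * 0.45;
  const double I_CaNa_sl = Fsl_CaL * ibarna_sl * d * f * (1.0 - fcasl) * 0.45;

  // NCX
  const double ibarncx = p[GP_GNCX] * IbarNCX * (1.0 + 0.4 * AF);
  const double Ka_junc = 1.0 / (1.0 + (Kdact / Caj) * (Kdact / Caj));
  const double Ka_sl = 1.0 / (1.0 + (Kdact / Casl) * (Kdact / Casl));
  const double Naj3 = Naj * Naj * Naj, Nasl3 = Nasl * Nasl * Nasl;
  const double Nao3 = Nao * Nao * Nao;
  const double s1_j = L[L_NCXE1] * Naj3 * Cao;
  const double s2_j = L[L_NCXE2] * Nao3 * Caj;
  const double s3_j = KmCai * Nao3 * (1.0 + std::pow(Naj / KmNai, 3.0)) +
                      KmNao * KmNao * KmNao * Caj * (1.0 + Caj / KmCai) +
                      KmCao * Naj3 + Naj3 * Cao + Nao3 * Caj;
  const double I_ncx_junc = Fjunc * ibarncx * Ka_junc * (s1_j - s2_j) /
                            (s3_j * (1.0 + ksat * L[L_NCXE2]));
  const double s1_sl = L[L_NCXE1] * Nasl3 * Cao;
  const double s2_sl = L[L_NCXE2] * Nao3 * Casl;
  const double s3_sl = KmCai * Nao3 * (1.0 + std::pow(Nasl / KmNai, 3.0)) +
                       KmNao * KmNao * KmNao * Casl * (1.0 + Casl / KmCai) +
                       KmCao * Nasl3 + Nasl3 * Cao + Nao3 * Casl;
  const double I_ncx_sl = Fsl * ibarncx * Ka_sl * (s1_sl - s2_sl) /
                          (s3_sl * (1.0 + ksat * L[L_NCXE2]));

  // sarcolemmal Ca pump + background
  const double caj16 = std::pow(Caj, 1.6), casl16 = std::pow(Casl, 1.6);
  const double km16 = std::pow(KmPCa, 1.6);
  const double I_pca_junc = Fjunc * IbarSLCaP * caj16 / (km16 + caj16);
  const double I_pca_sl = Fsl * IbarSLCaP * casl16 / (km16 + casl16);
  const double I_cabk_junc = Fjunc * GCaB * (v - eca_junc);
  const double I_cabk_sl = Fsl * GCaB * (v - eca_sl);

  // SR fluxes
  const double koCa = 10.0 + 20.0 * AF;
  const double kCaSR =
      MaxSR - (MaxSR - MinSR) / (1.0 + std::pow(ec50SR / Casr, 2.5));
  const double koSRCa = koCa / kCaSR;
  const double kiSRCa = kiCa * kCaSR;
  const double ryrr = y[S_RYRR], ryro = y[S_RYRO], ryri = y[S_RYRI];
  const double RI = 1.0 - ryrr - ryro - ryri;
  const double dRyRr = (kim * RI - kiSRCa * Caj * ryrr) -
                       (koSRCa * Caj * Caj * ryrr - kom * ryro);
  const double dRyRo = (koSRCa * Caj * Caj * ryrr - kom * ryro) -
                       (kiSRCa * Caj * ryro - kim * ryri);
  const double dRyRi = (kiSRCa * Caj * ryro - kim * ryri) -
                       (kom * ryri - koSRCa * Caj * Caj * RI);
  const double J_SRCarel = ks * ryro * (Casr - Caj);
  const double Kmf = (2.5 - 1.25 * ISO) * 0.246e-3;
  const double cf = std::pow(Cai / Kmf, hillSRCaP);
  const double cr = std::pow(Casr / Kmr, hillSRCaP);
  const double J_serca = p[GP_GUP] * Vmax_SRCaP * (cf - cr) / (1.0 + cf + cr);
  const double J_SRleak = (1.0 + 0.25 * AF) * 5.348e-6 * (Casr - Caj);

  // buffering fluxes
  const double dNaBj = kon_na * Naj * (Bmax_Naj - y[S_NABJ]) -
                       koff_na * y[S_NABJ];
  const double dNaBsl = kon_na * Nasl * (Bmax_Nasl - y[S_NABSL]) -
                        koff_na * y[S_NABSL];
  const double koff_tncl = (1.0 + 0.5 * ISO) * 19.6e-3;
  const double dTnCL = kon_tncl * Cai * (Bmax_TnClow - y[S_TNCL]) -
                       koff_tncl * y[S_TNCL];
  const double dTnCHc =
      kon_tnchca * Cai * (Bmax_TnChigh - y[S_TNCHC] - y[S_TNCHM]) -
      koff_tnchca * y[S_TNCHC];
  const double dTnCHm =
      kon_tnchmg * Mgi * (Bmax_TnChigh - y[S_TNCHC] - y[S_TNCHM]) -
      koff_tnchmg * y[S_TNCHM];
  const double dCaM = kon_cam * Cai * (Bmax_CaM - y[S_CAM]) -
                      koff_cam * y[S_CAM];
  const double dMyoc = kon_myoca * Cai * (Bmax_myosin - y[S_MYOC] - y[S_MYOM]) -
                       koff_myoca * y[S_MYOC];
  const double dMyom = kon_myomg * Mgi * (Bmax_myosin - y[S_MYOC] - y[S_MYOM]) -
                       koff_myomg * y[S_MYOM];
  const double dSRB = kon_sr * Cai * (Bmax_SR - y[S_SRB]) - koff_sr * y[S_SRB];
  const double J_CaB_cytosol = dTnCL + dTnCHc + dCaM + dMyoc + dSRB;

  const double dSLLj = kon_sll * Caj * (Bmax_SLlowj - y[S_SLLJ]) -
                       koff_sll * y[S_SLLJ];
  const double dSLLsl = kon_sll * Casl * (Bmax_SLlowsl - y[S_SLLSL]) -
                        koff_sll * y[S_SLLSL];
  const double dSLHj = kon_slh * Caj * (Bmax_SLhighj - y[S_SLHJ]) -
                       koff_slh * y[S_SLHJ];
  const double dSLHsl = kon_slh * Casl * (Bmax_SLhighsl - y[S_SLHSL]) -
                        koff_slh * y[S_SLHSL];
  const double J_CaB_junction = dSLLj + dSLHj;
  const double J_CaB_sl = dSLLsl + dSLHsl;

  const double dCsqnb = kon_csqn * Casr * (Bmax_Csqn - y[S_CSQNB]) -
                        koff_csqn * y[S_CSQNB];

  // current totals
  const double I_Na_tot_junc =
      I_Na_junc + I_nabk_junc + 3.0 * I_nak_junc + 3.0 * I_ncx_junc +
      I_CaNa_junc;
  const double I_Na_tot_sl =
      I_Na_sl + I_nabk_sl + 3.0 * I_nak_sl + 3.0 * I_ncx_sl + I_CaNa_sl;
  const double I_K_tot = I_to + I_kr + I_ks + I_ki - 2.0 * I_nak + I_CaK +
                         I_kp + I_kur;
  const double I_Ca_tot_junc =
      I_Ca_junc + I_cabk_junc + I_pca_junc - 2.0 * I_ncx_junc;
  const double I_Ca_tot_sl = I_Ca_sl + I_cabk_sl + I_pca_sl - 2.0 * I_ncx_sl;
  const double I_Cl_tot = I_ClCa + I_Clbk;
  const double I_tot = I_Na_tot_junc + I_Na_tot_sl + I_Cl_tot + I_K_tot +
                       I_Ca_tot_junc + I_Ca_tot_sl;

  // gate updates (Rush-Larsen for voltage gates, Euler for fca / RyR)
  y[S_M] = rl_step(m, L[L_MI], L[L_ME]);
  y[S_H] = rl_step(h, L[L_HI], L[L_HE]);
  y[S_J] = rl_step(j, L[L_JI], L[L_JE]);
  y[S_D] = rl_step(d, L[L_DI], L[L_DE]);
  y[S_F] = rl_step(f, L[L_FI], L[L_FE]);
  y[S_FCABJ] += dt * (1.7 * Caj * (1.0 - fcaj) - 11.9e-3 * fcaj);
  y[S_FCABSL] += dt * (1.7 * Casl * (1.0 - fcasl) - 11.9e-3 * fcasl);
  y[S_XTOF] = rl_step(y[S_XTOF], L[L_XTOFI], L[L_XTOFE]);
  y[S_YTOF] = rl_step(y[S_YTOF], L[L_YTOFI], L[L_YTOFE]);
  y[S_XKR] = rl_step(y[S_XKR], L[L_XKRI], L[L_XKRE]);
  y[S_XKS] = rl_step(xks, L[L_XKSI], L[L_XKSE]);
  y[S_XKUR] = rl_step(y[S_XKUR], L[L_XKURI], L[L_XKURE]);
  y[S_YKUR] = rl_step(y[S_YKUR], L[L_YKURI], L[L_YKURE]);
  y[S_RYRR] += dt * dRyRr;
  y[S_RYRO] += dt * dRyRo;
  y[S_RYRI] += dt * dRyRi;

  // buffers
  y[S_NABJ] += dt * dNaBj;
  y[S_NABSL] += dt * dNaBsl;
  y[S_TNCL] += dt * dTnCL;
  y[S_TNCHC] += dt * dTnCHc;
  y[S_TNCHM] += dt * dTnCHm;
  y[S_CAM] += dt * dCaM;
  y[S_MYOC] += dt * dMyoc;
  y[S_MYOM] += dt * dMyom;
  y[S_SRB] += dt * dSRB;
  y[S_SLLJ] += dt * dSLLj;
  y[S_SLLSL] += dt * dSLLsl;
  y[S_SLHJ] += dt * dSLHj;
  y[S_SLHSL] += dt * dSLHsl;
  y[S_CSQNB] += dt * dCsqnb;

  // SR and bulk concentrations
  y[S_CASR] += dt * (J_serca - (J_SRleak * Vmyo / Vsr + J_SRCarel) - dCsqnb);
  y[S_NAJ] += dt * (-I_Na_tot_junc * Cmem / (Vjunc * Frdy) +
                    J_na_juncsl / Vjunc * (Nasl - Naj) - dNaBj);
  y[S_NASL] += dt * (-I_Na_tot_sl * Cmem / (Vsl * Frdy) +
                     J_na_juncsl / Vsl * (Naj - Nasl) +
                     J_na_slmyo / Vsl * (Nai - Nasl) - dNaBsl);
  y[S_NAI] += dt * (J_na_slmyo / Vmyo * (Nasl - Nai));
  // bulk K+ held constant (standard for this model lineage)
  y[S_CAJ] += dt * (-I_Ca_tot_junc * Cmem / (Vjunc * 2.0 * Frdy) +
                    J_ca_juncsl / Vjunc * (Casl - Caj) - J_CaB_junction +
                    J_SRCarel * Vsr / Vjunc + J_SRleak * Vmyo / Vjunc);
  y[S_CASL] += dt * (-I_Ca_tot_sl * Cmem / (Vsl * 2.0 * Frdy) +
                     J_ca_juncsl / Vsl * (Caj - Casl) +
                     J_ca_slmyo / Vsl * (Cai - Casl) - J_CaB_sl);
  y[S_CAI] += dt * (-J_serca * Vsr / Vmyo - J_CaB_cytosol +
                    J_ca_slmyo / Vmyo * (Casl - Cai));

  y[S_V] += dt * (-I_tot + i_ext);
}

}  // namespace grandi

const CellModel& grandi_model() {
  static CellModel m = {grandi::N_STATE, grandi::N_LUT, grandi::default_state,
                        grandi::build_lut, grandi::step};
  return m;
}
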