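// Production right-hand side of the 33-state whole-cell model.
//
// Independent transcription of the reference implementation in
// R/model-core.R (the two are compared by an equivalence test).  Exposed two
// ways: (i) the deSolve compiled-code interface (cdx_initmod / cdx_derivs)
// used by the simulator, with the protocol schedule (piecewise environments
// joined by ouabain-like transitions) evaluated in C; (ii) an Rcpp
// single-point entry (cdx_rhs_point) for tests and current logging.

#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const char *PARAM_NAMES[] = {
  "R_gas", "Temp", "Frdy", "Cm", "V_c", "V_SR",
  "Na_o", "Ca_o", "K_o", "K_i",
  "g_Na", "g_NaL", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_f", "g_to",
  "P_NaK", "k_NCX", "g_pCa", "g_bNa", "g_bCa",
  "ncx_alpha", "ncx_gamma", "ncx_KmCa", "ncx_KmNai", "ncx_Ksat", "KpCa",
  "PkNa",
  "VmaxUp", "Kup", "V_leak", "g_irel",
  "RyR_amin", "RyR_aamp", "RyR_ac", "RyR_ak",
  "RyR_ohalf", "RyR_ok", "RyR_chalf", "RyR_ck", "RyR_srmid", "RyR_srk",
  "RyR_tauadapt", "RyR_tauact", "RyR_tauinact",
  "Buf_C", "Kbuf_C", "Buf_SR", "Kbuf_SR",
  "f_Na_frac", "na_inact_shift",
  "g_KATP", "katp_KoRef", "katp_KoExp", "katp_Km0", "katp_KmSlope",
  "katp_KmExp", "katp_H0", "katp_Hamp", "katp_Hslope",
  "serca_k1p", "serca_k2p", "serca_k1m", "serca_KdCai", "serca_KdCasr",
  "serca_KdHi", "serca_KdHsr", "serca_KdH1", "serca_KdATP", "serca_KdADP",
  "serca_KdPi", "serca_nH", "serca_dGATP0", "serca_S",
  "met_MgATP", "met_MgADP", "met_Pi", "met_pH",
  "ce_kon", "ce_koff", "ce_knp", "ce_kpn", "ce_perm50", "ce_nperm",
  "ce_fapp", "ce_gapp", "ce_hf", "ce_hb", "ce_PiRef", "ce_gxb", "ce_KdATP",
  "ce_KdADP", "ce_KdH", "ce_nHF", "ce_x0", "ce_kstrain", "ce_Tref",
  "ce_SL0", "ce_SLov", "ce_SLw", "ce_kpas", "ce_visc", "ce_rho_atp", "ce_basal",
  "ce_srx_on", "ce_srx_off", "ce_TrpnTot", "ce_xbfb",
  "o2_Omega", "o2_beta", "o2_epsilon", "o2_D", "o2_dx", "o2_source",
  "rho_a", "rho_b", "rho_c", "rho_K"
};
#define NPAR 120

static const char *MOD_NAMES[] = {
  "sc_gNa", "sc_gNaL", "sc_gCaL", "sc_gKr", "sc_gKs", "sc_gK1", "sc_gf",
  "sc_gto", "sc_PNaK", "sc_kNCX", "sc_gpCa", "sc_gbNa", "sc_gbCa",
  "sc_gKATP", "sc_girel", "sc_Iup", "sc_leak",
  "serca_k1p_mult", "serca_k2p_mult", "serca_KdHsr_mult", "serca_KdPi_mult",
  "serca_KdCai_mult",
  "K_o", "O2_s", "MgATP", "MgADP", "Pi", "pH",
  "kon_scale", "fkatp_scale", "f_NaK", "f_pCa"
};
#define NMOD 32
#define NOUT 26
#define NSTATE 33

// parameter indices (order must match PARAM_NAMES)
enum {
  iR_gas, iTemp, iFrdy, iCm, iV_c, iV_SR,
  iNa_o, iCa_o, iK_o_par, iK_i,
  ig_Na, ig_NaL, ig_CaL, ig_Kr, ig_Ks, ig_K1, ig_f, ig_to,
  iP_NaK, ik_NCX, ig_pCa, ig_bNa, ig_bCa,
  incx_alpha, incx_gamma, incx_KmCa, incx_KmNai, incx_Ksat, iKpCa,
  iPkNa,
  iVmaxUp, iKup, iV_leak, ig_irel,
  iRyR_amin, iRyR_aamp, iRyR_ac, iRyR_ak,
  iRyR_ohalf, iRyR_ok, iRyR_chalf, iRyR_ck, iRyR_srmid, iRyR_srk,
  iRyR_tauadapt, iRyR_tauact, iRyR_tauinact,
  iBuf_C, iKbuf_C, iBuf_SR, iKbuf_SR,
  if_Na_frac, ina_inact_shift,
  ig_KATP, ikatp_KoRef, ikatp_KoExp, ikatp_Km0, ikatp_KmSlope,
  ikatp_KmExp, ikatp_H0, ikatp_Hamp, ikatp_Hslope,
  iserca_k1p, iserca_k2p, iserca_k1m, iserca_KdCai, iserca_KdCasr,
  iserca_KdHi, iserca_KdHsr, iserca_KdH1, iserca_KdATP, iserca_KdADP,
  iserca_KdPi, iserca_nH, iserca_dGATP0, iserca_S,
  imet_MgATP, imet_MgADP, imet_Pi, imet_pH,
  ice_kon, ice_koff, ice_knp, ice_kpn, ice_perm50, ice_nperm,
  ice_fapp, ice_gapp, ice_hf, ice_hb, ice_PiRef, ice_gxb, ice_KdATP,
  ice_KdADP, ice_KdH, ice_nHF, ice_x0, ice_kstrain, ice_Tref,
  ice_SL0, ice_SLov, ice_SLw, ice_kpas, ice_visc, ice_rho_atp, ice_basal,
  ice_srx_on, ice_srx_off, ice_TrpnTot, ice_xbfb,
  io2_Omega, io2_beta, io2_epsilon, io2_D, io2_dx, io2_source,
  irho_a, irho_b, irho_c, irho_K
};

// modifier indices
enum {
  msc_gNa, msc_gNaL, msc_gCaL, msc_gKr, msc_gKs, msc_gK1, msc_gf,
  msc_gto, msc_PNaK, msc_kNCX, msc_gpCa, msc_gbNa, msc_gbCa,
  msc_gKATP, msc_girel, msc_Iup, msc_leak,
  mserca_k1p_mult, mserca_k2p_mult, mserca_KdHsr_mult, mserca_KdPi_mult,
  mserca_KdCai_mult,
  mK_o, mO2_s, mMgATP, mMgADP, mPi, mpH,
  mkon_scale, mfkatp_scale, mf_NaK, mf_pCa
};

// state indices
enum {
  S_V, S_Ca_SR, S_Ca_i, S_Na_i, S_m, S_h, S_j, S_mL, S_hL, S_d, S_f1, S_f2, S_fCa,
  S_Xr1, S_Xr2, S_Xs, S_Xf, S_q, S_r, S_RyR_a, S_RyR_o, S_RyR_c,
  S_trpn_T, S_trpn_TCa, S_xb_N, S_xb_P, S_xb_A, S_xb_B, S_x_A, S_x_B, S_SL,
  S_myo_SRX, S_O2_e
};

// ouabain-like (Michaelis ramp) transition shape on [0,1]
static inline double shape01(double s, double K) {
  if (s <= 0.0) return 0.0;
  if (s >= 1.0) return 1.0;
  return s * (1.0 + K) / (s + K);
}

// evaluate the schedule environment at time t into mod[NMOD].
// env: nrow plateaus (row-major, NMOD columns); breaks: 2*(nrow-1) times.
static void eval_schedule(double t, const double *env, int nrow,
                          const double *breaks, double K, double *mod) {
  if (nrow == 1) {
    for (int k = 0; k < NMOD; ++k) mod[k] = env[k];
    return;
  }
  int seg = 0; // number of completed transitions
  while (seg < nrow - 1 && t >= breaks[2 * seg + 1]) ++seg;
  if (seg < nrow - 1 && t > breaks[2 * seg]) {
    double t0 = breaks[2 * seg], t1 = breaks[2 * seg + 1];
    double w = shape01((t - t0) / (t1 - t0), K);
    for (int k = 0; k < NMOD; ++k) {
      double a = env[seg * NMOD + k], b = env[(seg + 1) * NMOD + k];
      mod[k] = a + (b - a) * w;
    }
  } else {
    for (int k = 0; k < NMOD; ++k) mod[k] = env[seg * NMOD + k];
  }
}

static double rho_curve(double O2s, const double *p) {
  double a = p[irho_a], b = p[irho_b], K = p[irho_K], c = p[irho_c];
  double x = O2s / p[io2_source];
  double raw = a + (b - a) / (1.0 + std::pow(x / K, -c));
  double base = a + (b - a) / (1.0 + std::pow(1.0 / K, -c));
  return raw / base;
}

// full RHS + outputs
static void rhs_eval(double t, const double *y, const double *p,
                     const double *m, double *dy, double *out) {
  (void)t;
  const double v = y[S_V], Vm = v * 1000.0;
  const double casr = y[S_Ca_SR];
  const double cai = y[S_Ca_i] > 1e-12 ? y[S_Ca_i] : 1e-12;
  const double nai = y[S_Na_i] > 1e-9 ? y[S_Na_i] : 1e-9;
  const double RT = p[iR_gas] * p[iTemp];
  const double RT_F = RT / p[iFrdy];
  const double ko = m[mK_o];

  const double E_Na = RT_F * std::log(p[iNa_o] / nai);
  const double E_K = RT_F * std::log(ko / p[iK_i]);
  const double E_Ks = RT_F * std::log((ko + p[iPkNa] * p[iNa_o]) /
                                      (p[iK_i] + p[iPkNa] * nai));
  const double E_Ca = 0.5 * RT_F * std::log(p[iCa_o] / cai);

  // I_Na
  double m_inf = std::pow(1.0 / (1.0 + std::exp((-Vm - 34.1) / 5.9)), 1.0 / 3.0);
  double alpha_m = 1.0 / (1.0 + std::exp((-Vm - 60.0) / 5.0));
  double beta_m = 0.1 / (1.0 + std::exp((Vm + 35.0) / 5.0)) +
                  0.1 / (1.0 + std::exp((Vm - 50.0) / 200.0));
  double tau_m = 1e-3 * alpha_m * beta_m;
  double h_inf = 1.0 / std::sqrt(1.0 + std::exp((Vm + 72.1 - p[ina_inact_shift]) / 5.7));
  double tau_h;
  if (v < -0.0385) {
    double ah = 0.057 * std::exp(-(Vm + 80.0) / 6.8);
    double bh = 2.7 * std::exp(0.079 * Vm) + 3.1e5 * std::exp(0.3485 * Vm);
    tau_h = 1.5 / ((ah + bh) * 1000.0);
  } else {
    tau_h = 2.542 / 1000.0;
  }
  double j_inf = h_inf, alpha_j, beta_j;
  if (v < -0.04) {
    alpha_j = (-25428.0 * std::exp(0.2444 * Vm) -
               6.948e-6 * std::exp(-0.04391 * Vm)) *
              (Vm + 37.78) / (1.0 + std::exp(0.311 * (Vm + 79.23)));
    beta_j = 0.02424 * std::exp(-0.01052 * Vm) /
             (1.0 + std::exp(-0.1378 * (Vm + 40.14)));
  } else {
    alpha_j = 0.0;
    beta_j = 0.6 * std::exp(0.057 * Vm) / (1.0 + std::exp(-0.1 * (Vm + 32.0)));
  }
  double tau_j = 7.0 / ((alpha_j + beta_j) * 1000.0);
  double i_Na = p[ig_Na] * m[msc_gNa] * y[S_m] * y[S_m] * y[S_m] * y[S_h] *
                y[S_j] * (v - E_Na);

  // I_NaL
  double mL_inf = 1.0 / (1.0 + std::exp((-Vm - 42.85) / 5.264));
  double tau_mL = tau_m;
  double hL_inf = 1.0 / (1.0 + std::exp((Vm + 87.61) / 7.488));
  double tau_hL = 0.2;
  double i_NaL = p[ig_NaL] * m[msc_gNaL] * y[S_mL] * y[S_mL] * y[S_mL] *
                 y[S_hL] * (v - E_Na);

  // I_CaL
  double d_inf = 1.0 / (1.0 + std::exp(-(Vm + 9.1) / 7.0));
  double alpha_d = 0.25 + 1.4 / (1.0 + std::exp((-Vm - 35.0) / 13.0));
  double beta_d = 1.4 / (1.0 + std::exp((Vm + 5.0) / 5.0));
  double gamma_d = 1.0 / (1.0 + std::exp((-Vm + 50.0) / 20.0));
  double tau_d = (alpha_d * beta_d + gamma_d) * 1e-3;
  double f1_inf = 1.0 / (1.0 + std::exp((Vm + 26.0) / 3.0));
  double constf1 = (f1_inf - y[S_f1] > 0.0) ? 1.0 + 1433.0 * (cai - 50e-6)
                                           : 1.0;
  double t15 = (Vm + 27.0) * (Vm + 27.0) / 225.0;
  double tau_f1 = (20.0 + 1102.5 * std::exp(-t15 * t15) +
                   200.0 / (1.0 + std::exp((13.0 - Vm) / 10.0)) +
                   180.0 / (1.0 + std::exp((30.0 + Vm) / 10.0))) *
                  constf1 * 1e-3;
  double f2_inf = 0.33 + 0.67 / (1.0 + std::exp((Vm + 32.0) / 4.0));
  double tau_f2 = (600.0 * std::exp(-(Vm + 25.0) * (Vm + 25.0) / 170.0) +
                   31.0 / (1.0 + std::exp((25.0 - Vm) / 10.0)) +
                   16.0 / (1.0 + std::exp((30.0 + Vm) / 10.0))) * 1e-3;
  double r8 = cai / 0.0006;
  r8 = r8 * r8; r8 = r8 * r8; r8 = r8 * r8;
  double alpha_fCa = 1.0 / (1.0 + r8);
  double beta_fCa = 0.1 / (1.0 + std::exp((cai - 0.0009) / 0.0002));
  double gamma_fCa = 0.3 / (1.0 + std::exp((cai - 0.00075) / 0.0008));
  double fCa_inf = (alpha_fCa + beta_fCa + gamma_fCa) / 1.3156;
  double constfCa = (v > -0.06 && fCa_inf > y[S_fCa]) ? 0.0 : 1.0;
  double tau_fCa = 0.002;
  double two_vfrt = 2.0 * v * p[iFrdy] / RT;
  double vv = std::fabs(v) < 1e-9 ? 1e-9 : v;
  double expden = std::exp(two_vfrt) - 1.0;
  if (std::fabs(expden) < 1e-12) expden = 1e-12;
  double i_CaL = p[ig_CaL] * m[msc_gCaL] * 4.0 * vv * p[iFrdy] * p[iFrdy] /
                 RT * (cai * std::exp(two_vfrt) - 0.341 * p[iCa_o]) /
                 expden * y[S_d] * y[S_f1] * y[S_f2] * y[S_fCa];

  // I_Kr
  double L0 = 0.025, Qf = 2.3;
  double ca_o = p[iCa_o];
  double v_half = 1000.0 * (-RT_F / Qf *
    std::log(std::pow(1.0 + ca_o / 2.6, 4.0) /
             (L0 * std::pow(1.0 + ca_o / 0.58, 4.0))) - 0.019);
  double Xr1_inf = 1.0 / (1.0 + std::exp((v_half - Vm) / 4.9));
  double alpha_Xr1 = 450.0 / (1.0 + std::exp((-45.0 - Vm) / 10.0));
  double beta_Xr1 = 6.0 / (1.0 + std::exp((Vm + 30.0) / 11.5));
  double tau_Xr1 = alpha_Xr1 * beta_Xr1 * 1e-3;
  double Xr2_inf = 1.0 / (1.0 + std::exp((Vm + 88.0) / 50.0));
  double alpha_Xr2 = 3.0 / (1.0 + std::exp((-60.0 - Vm) / 20.0));
  double beta_Xr2 = 1.12 / (1.0 + std::exp((Vm - 60.0) / 20.0));
  double tau_Xr2 = alpha_Xr2 * beta_Xr2 * 1e-3;
  double i_Kr = p[ig_Kr] * m[msc_gKr] * std::sqrt(ko / 5.4) * y[S_Xr1] *
                y[S_Xr2] * (v - E_K);

  // I_Ks
  double Xs_inf = 1.0 / (1.0 + std::exp((-Vm - 20.0) / 16.0));
  double alpha_Xs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - Vm) / 6.0));
  double beta_Xs = 1.0 / (1.0 + std::exp((Vm - 60.0) / 20.0));
  double tau_Xs = alpha_Xs * beta_Xs * 1e-3;
  double i_Ks = p[ig_Ks] * m[msc_gKs] * y[S_Xs] * y[S_Xs] * (v - E_Ks) *
                (1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4)));

  // I_K1
  double dvk = Vm - E_K * 1000.0;
  double alpha_K1 = 3.91 / (1.0 + std::exp(0.5942 * (dvk - 200.0)));
  double beta_K1 = (-1.509 * std::exp(0.0002 * (dvk + 100.0)) +
                    std::exp(0.5886 * (dvk - 10.0))) /
                   (1.0 + std::exp(0.4547 * dvk));
  double XK1_inf = alpha_K1 / (alpha_K1 + beta_K1);
  double i_K1 = p[ig_K1] * m[msc_gK1] * XK1_inf * (v - E_K) *
                std::sqrt(ko / 5.4);

  // I_f
  double Xf_inf = 1.0 / (1.0 + std::exp((Vm + 77.85) / 5.0));
  double tau_Xf = (1900.0 / (1.0 + std::exp((Vm + 15.0) / 10.0))) * 1e-3;
  double gf = p[ig_f] * m[msc_gf] * y[S_Xf];
  double i_fNa = p[if_Na_frac] * gf * (v - E_Na);
  double i_fK = (1.0 - p[if_Na_frac]) * gf * (v - E_K);
  double i_f = i_fNa + i_fK;

  // I_to
  double q_inf = 1.0 / (1.0 + std::exp((Vm + 53.0) / 13.0));
  double tau_q = (6.06 + 39.102 /
                  (0.57 * std::exp(-0.08 * (Vm + 44.0)) +
                   0.065 * std::exp(0.1 * (Vm + 45.93)))) * 1e-3;
  double r_inf = 1.0 / (1.0 + std::exp(-(Vm - 22.3) / 18.75));
  double tau_r = (2.75352 + 14.40516 /
                  (1.037 * std::exp(0.09 * (Vm + 30.61)) +
                   0.369 * std::exp(-0.12 * (Vm + 23.84)))) * 1e-3;
  double i_to = p[ig_to] * m[msc_gto] * y[S_q] * y[S_r] * (v - E_K);

  // pumps & exchangers
  double rho = rho_curve(m[mO2_s], p);
  double f_NaK = rho * m[mf_NaK];
  double f_pCa = rho * m[mf_pCa];
  double vfrt = v * p[iFrdy] / RT;
  double i_NaK = f_NaK * p[iP_NaK] * m[msc_PNaK] * ko / (ko + 1.0) *
                 nai / (nai + 40.0) /
                 (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                  0.0353 * std::exp(-vfrt));
  double gam = p[incx_gamma];
  double nao3 = p[iNa_o] * p[iNa_o] * p[iNa_o];
  double i_NCX = p[ik_NCX] * m[msc_kNCX] *
    (std::exp(gam * vfrt) * nai * nai * nai * ca_o -
     std::exp((gam - 1.0) * vfrt) * nao3 * cai * p[incx_alpha]) /
    ((p[incx_KmNai] * p[incx_KmNai] * p[incx_KmNai] + nao3) *
     (p[incx_KmCa] + ca_o) *
     (1.0 + p[incx_Ksat] * std::exp((gam - 1.0) * vfrt)));
  double i_pCa = f_pCa * p[ig_pCa] * m[msc_gpCa] * cai / (cai + p[iKpCa]);
  double i_bNa = p[ig_bNa] * m[msc_gbNa] * (v - E_Na);
  double i_bCa = p[ig_bCa] * m[msc_gbCa] * (v - E_Ca);

  // I_KATP (Ferrero-lineage nucleotide gating)
  double atp_uM = m[mMgATP] * 1e3, adp_uM = m[mMgADP] * 1e3;
  double Km = p[ikatp_Km0] + p[ikatp_KmSlope] * std::pow(adp_uM, p[ikatp_KmExp]);
  double Hh = p[ikatp_H0] + p[ikatp_Hamp] * std::exp(-p[ikatp_Hslope] * adp_uM);
  double fk = 1.0 / (1.0 + std::pow(atp_uM / Km, Hh));
  double i_KATP = p[ig_KATP] * m[msc_gKATP] *
                  std::pow(ko / p[ikatp_KoRef], p[ikatp_KoExp]) *
                  fk * m[mfkatp_scale] * (v - E_K);

  // SERCA two-state pump (Haldane-consistent)
  double k1p = p[iserca_k1p] * m[mserca_k1p_mult];
  double k2p = p[iserca_k2p] * m[mserca_k2p_mult];
  double KdHsr = p[iserca_KdHsr] * m[mserca_KdHsr_mult];
  double KdPi = p[iserca_KdPi] * m[mserca_KdPi_mult];
  double KdCai = p[iserca_KdCai] * m[mserca_KdCai_mult];
  double Hi = std::pow(10.0, -m[mpH]) * 1e3;
  double nHs = p[iserca_nH];
  double phiCai = (cai / KdCai) * (cai / KdCai);
  double phiCasr = (casr / p[iserca_KdCasr]) * (casr / p[iserca_KdCasr]);
  double phiHi = std::pow(Hi / p[iserca_KdHi], nHs);
  double phiHsr = std::pow(Hi / KdHsr, nHs);
  double aATP = m[mMgATP] / p[iserca_KdATP];
  double aADP = m[mMgADP] / p[iserca_KdADP];
  double aPi = m[mPi] / KdPi;
  double modH = 1.0 / (1.0 + Hi / p[iserca_KdH1]);
  double Dcyt = 1.0 + phiHi + phiCai * (1.0 + aATP);
  double Dsr = 1.0 + phiHsr + phiCasr * (1.0 + aADP);
  double keq_mM = std::exp(-p[iserca_dGATP0] / RT) * 1e3;
  double K0 = keq_mM *
    (KdCai * KdCai * p[iserca_KdATP] *
     std::pow(KdHsr, nHs)) /
    (p[iserca_KdCasr] * p[iserca_KdCasr] * p[iserca_KdADP] * KdPi *
     std::pow(p[iserca_KdHi], nHs));
  double k2m = k1p * k2p / (p[iserca_k1m] * K0);
  double ap1 = k1p * phiCai * aATP / Dcyt;
  double ap2 = k2p * phiHsr * modH / Dsr;
  double am1 = p[iserca_k1m] * phiCasr * aADP / Dsr;
  double am2 = k2m * phiHi * aPi * modH / Dcyt;
  double den = ap1 + ap2 + am1 + am2;
  double v_cle = den > 0.0 ? (ap1 * ap2 - am1 * am2) / den : 0.0;
  double psp = den > 0.0 ? (ap1 + am2) / den : NA_REAL;
  double i_up = p[iserca_S] * v_cle * m[msc_Iup];

  // RyR release + leak
  double c_uM = cai * 1000.0;
  double sr_sens = 1.0 - 1.0 / (1.0 + std::exp((casr - p[iRyR_srmid]) / p[iRyR_srk]));
  double a_inf = p[iRyR_amin] + p[iRyR_aamp] /
                 (1.0 + std::exp(-(c_uM - p[iRyR_ac]) / p[iRyR_ak]));
  double o_inf = 1.0 /
                 (1.0 + std::exp(-(c_uM - (y[S_RyR_a] + p[iRyR_ohalf])) /
                                 p[iRyR_ok]));
  double c_inf = 1.0 /
                 (1.0 + std::exp((c_uM - (y[S_RyR_a] + p[iRyR_chalf])) /
                                 p[iRyR_ck]));
  double i_rel = p[ig_irel] * m[msc_girel] * sr_sens * y[S_RyR_o] *
                 y[S_RyR_c] * (casr - cai);
  double i_leak = p[iV_leak] * m[msc_leak] * (casr - cai);

  // contractile element
  double H_i_ce = Hi;
  double kon = p[ice_kon] * m[mkon_scale];
  double xb_load = y[S_xb_A] + y[S_xb_B];
  double kfb = 1.0 - p[ice_xbfb] * xb_load;
  if (kfb < 0.1) kfb = 0.1;
  double dTCa = kon * cai * y[S_trpn_T] - p[ice_koff] * kfb * y[S_trpn_TCa];
  double tca = y[S_trpn_TCa] > 0.0 ? y[S_trpn_TCa] : 0.0;
  double ntr = p[ice_nperm];
  double tcan = std::pow(tca, ntr);
  double perm = tcan / (tcan + std::pow(p[ice_perm50], ntr));
  double k_np = p[ice_knp] * perm;
  double k_pn = p[ice_kpn] * (1.0 - perm);
  double drx = 1.0 - y[S_myo_SRX];
  double f_app = p[ice_fapp] * drx;
  double g_app = p[ice_gapp];
  double h_f = p[ice_hf];
  double h_b = p[ice_hb] * m[mPi] / p[ice_PiRef];
  double g_xb = p[ice_gxb] * m[mMgATP] / (m[mMgATP] + p[ice_KdATP]) /
                (1.0 + m[mMgADP] / p[ice_KdADP]);
  double N = y[S_xb_N], P = y[S_xb_P], A = y[S_xb_A], B = y[S_xb_B];
  double dN = k_pn * P - k_np * N;
  double dP = k_np * N - k_pn * P - f_app * P + g_app * A + g_xb * B;
  double dA = f_app * P - (g_app + h_f) * A + h_b * B;
  double dB = h_f * A - (h_b + g_xb) * B;
  double dev = (y[S_SL] - p[ice_SLov]) / p[ice_SLw];
  double ov = std::exp(-0.5 * dev * dev);
  double hfac = 1.0 / (1.0 + std::pow(H_i_ce / p[ice_KdH], p[ice_nHF]));
  double tension = p[ice_Tref] * ov * hfac *
                   (A * y[S_x_A] + B * y[S_x_B]) / p[ice_x0];
  if (tension < 0.0) tension = 0.0;
  double dSL = (p[ice_kpas] * (p[ice_SL0] - y[S_SL]) - tension) / p[ice_visc];
  double dxA = 0.5 * dSL - p[ice_kstrain] * y[S_x_A];
  double dxB = 0.5 * dSL + p[ice_kstrain] * (p[ice_x0] - y[S_x_B]);
  double dSRX = p[ice_srx_on] * (1.0 - y[S_myo_SRX]) -
                p[ice_srx_off] * y[S_myo_SRX];
  double ATPase = p[ice_rho_atp] * (g_xb * B + p[ice_basal] * drx *
                   m[mMgATP] / (m[mMgATP] + p[ice_KdATP]));
  double shortening = 100.0 * (p[ice_SL0] - y[S_SL]) / p[ice_SL0];
  double J_trpn = p[ice_TrpnTot] * dTCa;

  // balances
  double gamma_chg = p[iCm] / (p[iFrdy] * p[iV_c] * 1e-18);
  double kb = cai + p[iKbuf_C];
  double bufc = 1.0 / (1.0 + p[iBuf_C] * p[iKbuf_C] / (kb * kb));
  double kbs = casr + p[iKbuf_SR];
  double bufsr = 1.0 / (1.0 + p[iBuf_SR] * p[iKbuf_SR] / (kbs * kbs));
  double dCai = bufc * (i_leak - i_up + i_rel - J_trpn -
                        (i_CaL + i_bCa + i_pCa - 2.0 * i_NCX) *
                        gamma_chg / 2.0);
  double dCaSR = bufsr * (p[iV_c] / p[iV_SR]) * (i_up - i_rel - i_leak);
  double dNai = -(i_Na + i_NaL + i_bNa + 3.0 * i_NaK + 3.0 * i_NCX + i_fNa) *
                gamma_chg;
  double dO2 = p[io2_epsilon] * (m[mO2_s] - y[S_O2_e]) -
               p[io2_Omega] * (p[io2_beta] * gamma_chg *
                               (i_NaK + i_pCa) + ATPase);

  double i_tot = i_Na + i_NaL + i_CaL + i_Kr + i_Ks + i_K1 + i_f + i_to +
                 i_NaK + i_NCX + i_pCa + i_bNa + i_bCa + i_KATP;

  dy[S_V] = -i_tot;
  dy[S_Ca_SR] = dCaSR;
  dy[S_Ca_i] = dCai;
  dy[S_Na_i] = dNai;
  dy[S_m] = (m_inf - y[S_m]) / tau_m;
  dy[S_h] = (h_inf - y[S_h]) / tau_h;
  dy[S_j] = (j_inf - y[S_j]) / tau_j;
  dy[S_mL] = (mL_inf - y[S_mL]) / tau_mL;
  dy[S_hL] = (hL_inf - y[S_hL]) / tau_hL;
  dy[S_d] = (d_inf - y[S_d]) / tau_d;
  dy[S_f1] = (f1_inf - y[S_f1]) / tau_f1;
  dy[S_f2] = (f2_inf - y[S_f2]) / tau_f2;
  dy[S_fCa] = constfCa * (fCa_inf - y[S_fCa]) / tau_fCa;
  dy[S_Xr1] = (Xr1_inf - y[S_Xr1]) / tau_Xr1;
  dy[S_Xr2] = (Xr2_inf - y[S_Xr2]) / tau_Xr2;
  dy[S_Xs] = (Xs_inf - y[S_Xs]) / tau_Xs;
  dy[S_Xf] = (Xf_inf - y[S_Xf]) / tau_Xf;
  dy[S_q] = (q_inf - y[S_q]) / tau_q;
  dy[S_r] = (r_inf - y[S_r]) / tau_r;
  dy[S_RyR_a] = (a_inf - y[S_RyR_a]) / p[iRyR_tauadapt];
  dy[S_RyR_o] = (o_inf - y[S_RyR_o]) / p[iRyR_tauact];
  dy[S_RyR_c] = (c_inf - y[S_RyR_c]) / p[iRyR_tauinact];
  dy[S_trpn_T] = -dTCa;
  dy[S_trpn_TCa] = dTCa;
  dy[S_xb_N] = dN;
  dy[S_xb_P] = dP;
  dy[S_xb_A] = dA;
  dy[S_xb_B] = dB;
  dy[S_x_A] = dxA;
  dy[S_x_B] = dxB;
  dy[S_SL] = dSL;
  dy[S_myo_SRX] = dSRX;
  dy[S_O2_e] = dO2;

  if (out) {
    out[0] = i_Na; out[1] = i_NaL; out[2] = i_CaL; out[3] = i_Kr;
    out[4] = i_Ks; out[5] = i_K1; out[6] = i_f; out[7] = i_to;
    out[8] = i_NaK; out[9] = i_NCX; out[10] = i_pCa; out[11] = i_bNa;
    out[12] = i_bCa; out[13] = i_KATP; out[14] = i_rel; out[15] = i_up;
    out[16] = i_leak; out[17] = tension; out[18] = ATPase;
    out[19] = shortening; out[20] = dO2; out[21] = rho; out[22] = fk;
    out[23] = v_cle; out[24] = psp; out[25] = J_trpn;
  }
}

// ---- deSolve compiled interface ------------------------------------------
// The parameter/schedule block is staged from R via cdx_set_parms() before
// integration (layout: [nrow, nwin, p(NPAR), env(nrow*NMOD row-major),
// breaks(2*nwin)]); the solver is then called with parms = NULL.
static std::vector<double> g_parms;

//' @noRd
// [[Rcpp::export(name = "cdx_set_parms_cpp")]]
void cdx_set_parms_cpp(NumericVector parms) {
  int n = parms.size();
  if (n < 2 + NPAR) stop("parameter block too short");
  int nrow = (int)parms[0], nwin = (int)parms[1];
  if (n != 2 + NPAR + nrow * NMOD + 2 * nwin)
    stop("parameter block length inconsistent with its header");
  g_parms.assign(parms.begin(), parms.end());
}

extern "C" {

void cdx_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
                int *ip) {
  (void)neq;
  const double *par = g_parms.data();
  int nrow = (int)par[0], nwin = (int)par[1];
  const double *p = par + 2;
  const double *env = p + NPAR;
  const double *breaks = env + nrow * NMOD;
  (void)nwin;
  double mod[NMOD];
  eval_schedule(*t, env, nrow, breaks, p[irho_K], mod);
  double *out = (ip[0] >= NOUT) ? yout : (double *)0;
  rhs_eval(*t, y, p, mod, ydot, out);
}

} // extern "C"

// ---- Rcpp entry points ----------------------------------------------------

//' @noRd
// [[Rcpp::export(name = "cdx_cpp_param_names")]]
CharacterVector cdx_cpp_param_names() {
  return CharacterVector(PARAM_NAMES, PARAM_NAMES + NPAR);
}

//' @noRd
// [[Rcpp::export(name = "cdx_cpp_mod_names")]]
CharacterVector cdx_cpp_mod_names() {
  return CharacterVector(MOD_NAMES, MOD_NAMES + NMOD);
}

//' @noRd
// [[Rcpp::export(name = "cdx_rhs_point_cpp")]]
List cdx_rhs_point_cpp(double t, NumericVector y, NumericVector p,
                       NumericVector mod) {
  if (y.size() != NSTATE) stop("state vector must have 33 entries");
  if (p.size() != NPAR) stop("parameter vector length mismatch");
  if (mod.size() != NMOD) stop("modifier vector length mismatch");
  NumericVector dy(NSTATE), out(NOUT);
  rhs_eval(t, REAL(y), REAL(p), REAL(mod), REAL(dy), REAL(out));
  return List::create(_["dy"] = dy, _["out"] = out);
}

//' @noRd
// [[Rcpp::export(name = "cdx_schedule_eval_cpp")]]
NumericVector cdx_schedule_eval_cpp(double t, NumericMatrix env,
                                    NumericVector breaks, double K) {
  if (env.ncol() != NMOD) stop("environment matrix column count mismatch");
  // copy row-major
  int nrow = env.nrow();
  std::vector<double> envr((size_t)nrow * NMOD);
  for (int i = 0; i < nrow; ++i)
    for (int k = 0; k < NMOD; ++k) envr[(size_t)i * NMOD + k] = env(i, k);
  NumericVector mod(NMOD);
  eval_schedule(t, envr.data(), nrow, REAL(breaks), K, REAL(mod));
  return mod;
}
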