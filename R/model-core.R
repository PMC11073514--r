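# Whole-cell right-hand side (reference R implementation).
#
# Paci-family hiPSC-CM electrophysiology (SI units: volts, seconds; gate
# kinetics in mV via V*1000) + two-state SERCA + mean-field CE + oxygen
# balance.  A second, independent transcription of the same equations lives
# in src/rhs.cpp and is the production integration path; the two are held
# together by an equivalence test.

cdx_current_names <- function() {
  c("I_Na", "I_NaL", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_f", "I_to",
    "I_NaK", "I_NCX", "I_pCa", "I_bNa", "I_bCa", "I_KATP",
    "I_rel", "I_up", "I_leak",
    "tension", "ATPase", "shortening", "OCR", "rho", "f_KATP",
    "v_cle", "PSP", "J_trpn")
}

# core evaluation: returns list(dy, out)
rhs_core_r <- function(t, y, p, m) {
  v  <- y[["V"]];    Vm <- v * 1000
  casr <- y[["Ca_SR"]]; cai <- max(y[["Ca_i"]], 1e-12)
  nai  <- max(y[["Na_i"]], 1e-9)
  RT_F <- p[["R_gas"]] * p[["Temp"]] / p[["Frdy"]]

  ko <- m[["K_o"]]
  E_Na <- RT_F * log(p[["Na_o"]] / nai)
  E_K  <- RT_F * log(ko / p[["K_i"]])
  E_Ks <- RT_F * log((ko + p[["PkNa"]] * p[["Na_o"]]) /
                     (p[["K_i"]] + p[["PkNa"]] * nai))
  E_Ca <- 0.5 * RT_F * log(p[["Ca_o"]] / cai)

  ## --- I_Na (m^3 h j) ---------------------------------------------------
  m_inf <- (1 / (1 + exp((-Vm - 34.1) / 5.9)))^(1 / 3)
  alpha_m <- 1 / (1 + exp((-Vm - 60) / 5))
  beta_m <- 0.1 / (1 + exp((Vm + 35) / 5)) + 0.1 / (1 + exp((Vm - 50) / 200))
  tau_m <- 1e-3 * alpha_m * beta_m
  h_inf <- 1 / sqrt(1 + exp((Vm + 72.1 - p[["na_inact_shift"]]) / 5.7))
  if (v < -0.0385) {
    alpha_h <- 0.057 * exp(-(Vm + 80) / 6.8)
    beta_h <- 2.7 * exp(0.079 * Vm) + 3.1e5 * exp(0.3485 * Vm)
    tau_h <- 1.5 / ((alpha_h + beta_h) * 1000)
  } else {
    alpha_h <- 0
    beta_h <- 0.77 / (0.13 * (1 + exp((Vm + 10.66) / -11.1)))
    tau_h <- 2.542 / 1000
  }
  j_inf <- h_inf
  if (v < -0.04) {
    alpha_j <- (-25428 * exp(0.2444 * Vm) - 6.948e-6 * exp(-0.04391 * Vm)) *
      (Vm + 37.78) / (1 + exp(0.311 * (Vm + 79.23)))
    beta_j <- 0.02424 * exp(-0.01052 * Vm) /
      (1 + exp(-0.1378 * (Vm + 40.14)))
  } else {
    alpha_j <- 0
    beta_j <- 0.6 * exp(0.057 * Vm) / (1 + exp(-0.1 * (Vm + 32)))
  }
  tau_j <- 7 / ((alpha_j + beta_j) * 1000)
  i_Na <- p[["g_Na"]] * m[["sc_gNa"]] * y[["m"]]^3 * y[["h"]] * y[["j"]] *
    (v - E_Na)

  ## --- I_NaL (mL^3 hL) --------------------------------------------------
  mL_inf <- 1 / (1 + exp((-Vm - 42.85) / 5.264))
  tau_mL <- tau_m
  hL_inf <- 1 / (1 + exp((Vm + 87.61) / 7.488))
  tau_hL <- 0.2
  i_NaL <- p[["g_NaL"]] * m[["sc_gNaL"]] * y[["mL"]]^3 * y[["hL"]] *
    (v - E_Na)

  ## --- I_CaL (GHK driving force) ----------------------------------------
  d_inf <- 1 / (1 + exp(-(Vm + 9.1) / 7))
  alpha_d <- 0.25 + 1.4 / (1 + exp((-Vm - 35) / 13))
  beta_d <- 1.4 / (1 + exp((Vm + 5) / 5))
  gamma_d <- 1 / (1 + exp((-Vm + 50) / 20))
  tau_d <- (alpha_d * beta_d + gamma_d) * 1e-3
  f1_inf <- 1 / (1 + exp((Vm + 26) / 3))
  constf1 <- if (f1_inf - y[["f1"]] > 0) 1 + 1433 * (cai - 50e-6) else 1
  tau_f1 <- (20 + 1102.5 * exp(-((Vm + 27)^2 / 15^2)^2) +
             200 / (1 + exp((13 - Vm) / 10)) +
             180 / (1 + exp((30 + Vm) / 10))) * constf1 * 1e-3
  f2_inf <- 0.33 + 0.67 / (1 + exp((Vm + 32) / 4))
  tau_f2 <- (600 * exp(-(Vm + 25)^2 / 170) +
             31 / (1 + exp((25 - Vm) / 10)) +
             16 / (1 + exp((30 + Vm) / 10))) * 1e-3
  alpha_fCa <- 1 / (1 + (cai / 0.0006)^8)
  beta_fCa <- 0.1 / (1 + exp((cai - 0.0009) / 0.0002))
  gamma_fCa <- 0.3 / (1 + exp((cai - 0.00075) / 0.0008))
  fCa_inf <- (alpha_fCa + beta_fCa + gamma_fCa) / 1.3156
  constfCa <- if (v > -0.06 && fCa_inf > y[["fCa"]]) 0 else 1
  tau_fCa <- 0.002
  two_vfrt <- 2 * v * p[["Frdy"]] / (p[["R_gas"]] * p[["Temp"]])
  vv <- if (abs(v) < 1e-9) 1e-9 else v
  i_CaL <- p[["g_CaL"]] * m[["sc_gCaL"]] *
    4 * vv * p[["Frdy"]]^2 / (p[["R_gas"]] * p[["Temp"]]) *
    (cai * exp(two_vfrt) - 0.341 * p[["Ca_o"]]) / (exp(two_vfrt) - 1 +
      (abs(two_vfrt) < 1e-12) * 1e-12) *
    y[["d"]] * y[["f1"]] * y[["f2"]] * y[["fCa"]]

  ## --- I_Kr -------------------------------------------------------------
  L0 <- 0.025; Qf <- 2.3
  v_half <- 1000 * (-RT_F / Qf *
    log((1 + p[["Ca_o"]] / 2.6)^4 / (L0 * (1 + p[["Ca_o"]] / 0.58)^4)) -
    0.019)
  Xr1_inf <- 1 / (1 + exp((v_half - Vm) / 4.9))
  alpha_Xr1 <- 450 / (1 + exp((-45 - Vm) / 10))
  beta_Xr1 <- 6 / (1 + exp((Vm + 30) / 11.5))
  tau_Xr1 <- alpha_Xr1 * beta_Xr1 * 1e-3
  Xr2_inf <- 1 / (1 + exp((Vm + 88) / 50))
  alpha_Xr2 <- 3 / (1 + exp((-60 - Vm) / 20))
  beta_Xr2 <- 1.12 / (1 + exp((Vm - 60) / 20))
  tau_Xr2 <- alpha_Xr2 * beta_Xr2 * 1e-3
  i_Kr <- p[["g_Kr"]] * m[["sc_gKr"]] * sqrt(ko / 5.4) *
    y[["Xr1"]] * y[["Xr2"]] * (v - E_K)

  ## --- I_Ks -------------------------------------------------------------
  Xs_inf <- 1 / (1 + exp((-Vm - 20) / 16))
  alpha_Xs <- 1100 / sqrt(1 + exp((-10 - Vm) / 6))
  beta_Xs <- 1 / (1 + exp((Vm - 60) / 20))
  tau_Xs <- alpha_Xs * beta_Xs * 1e-3
  i_Ks <- p[["g_Ks"]] * m[["sc_gKs"]] * y[["Xs"]]^2 * (v - E_Ks) *
    (1 + 0.6 / (1 + (3.8e-5 / cai)^1.4))

  ## --- I_K1 (instantaneous) ----------------------------------------------
  dvk <- Vm - E_K * 1000
  alpha_K1 <- 3.91 / (1 + exp(0.5942 * (dvk - 200)))
  beta_K1 <- (-1.509 * exp(0.0002 * (dvk + 100)) + exp(0.5886 * (dvk - 10))) /
    (1 + exp(0.4547 * dvk))
  XK1_inf <- alpha_K1 / (alpha_K1 + beta_K1)
  i_K1 <- p[["g_K1"]] * m[["sc_gK1"]] * XK1_inf * (v - E_K) * sqrt(ko / 5.4)

  ## --- I_f (Na/K mixed) ---------------------------------------------------
  Xf_inf <- 1 / (1 + exp((Vm + 77.85) / 5))
  tau_Xf <- (1900 / (1 + exp((Vm + 15) / 10))) * 1e-3
  gf <- p[["g_f"]] * m[["sc_gf"]] * y[["Xf"]]
  i_fNa <- p[["f_Na_frac"]] * gf * (v - E_Na)
  i_fK <- (1 - p[["f_Na_frac"]]) * gf * (v - E_K)
  i_f <- i_fNa + i_fK

  ## --- I_to ---------------------------------------------------------------
  q_inf <- 1 / (1 + exp((Vm + 53) / 13))
  tau_q <- (6.06 + 39.102 / (0.57 * exp(-0.08 * (Vm + 44)) +
                             0.065 * exp(0.1 * (Vm + 45.93)))) * 1e-3
  r_inf <- 1 / (1 + exp(-(Vm - 22.3) / 18.75))
  tau_r <- (2.75352 + 14.40516 / (1.037 * exp(0.09 * (Vm + 30.61)) +
                                  0.369 * exp(-0.12 * (Vm + 23.84)))) * 1e-3
  i_to <- p[["g_to"]] * m[["sc_gto"]] * y[["q"]] * y[["r"]] * (v - E_K)

  ## --- pumps & exchangers --------------------------------------------------
  rho_o2 <- cdx_rho(m[["O2_s"]], p)
  f_NaK <- rho_o2 * m[["f_NaK"]]
  f_pCa <- rho_o2 * m[["f_pCa"]]
  vfrt <- v * p[["Frdy"]] / (p[["R_gas"]] * p[["Temp"]])
  i_NaK <- f_NaK * p[["P_NaK"]] * m[["sc_PNaK"]] * ko / (ko + 1) *
    nai / (nai + 40) /
    (1 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt))
  gam <- p[["ncx_gamma"]]
  i_NCX <- p[["k_NCX"]] * m[["sc_kNCX"]] *
    (exp(gam * vfrt) * nai^3 * p[["Ca_o"]] -
     exp((gam - 1) * vfrt) * p[["Na_o"]]^3 * cai * p[["ncx_alpha"]]) /
    ((p[["ncx_KmNai"]]^3 + p[["Na_o"]]^3) * (p[["ncx_KmCa"]] + p[["Ca_o"]]) *
     (1 + p[["ncx_Ksat"]] * exp((gam - 1) * vfrt)))
  i_pCa <- f_pCa * p[["g_pCa"]] * m[["sc_gpCa"]] * cai / (cai + p[["KpCa"]])
  i_bNa <- p[["g_bNa"]] * m[["sc_gbNa"]] * (v - E_Na)
  i_bCa <- p[["g_bCa"]] * m[["sc_gbCa"]] * (v - E_Ca)

  ## --- I_KATP -------------------------------------------------------------
  fk <- cdx_f_katp(m[["MgATP"]], m[["MgADP"]], p)
  i_KATP <- p[["g_KATP"]] * m[["sc_gKATP"]] *
    (ko / p[["katp_KoRef"]])^p[["katp_KoExp"]] *
    fk * m[["fkatp_scale"]] * (v - E_K)

  ## --- SERCA (two-state thermodynamic pump) --------------------------------
  ps <- p
  ps[["serca_k1p"]] <- p[["serca_k1p"]] * m[["serca_k1p_mult"]]
  ps[["serca_k2p"]] <- p[["serca_k2p"]] * m[["serca_k2p_mult"]]
  ps[["serca_KdHsr"]] <- p[["serca_KdHsr"]] * m[["serca_KdHsr_mult"]]
  ps[["serca_KdPi"]] <- p[["serca_KdPi"]] * m[["serca_KdPi_mult"]]
  ps[["serca_KdCai"]] <- p[["serca_KdCai"]] * m[["serca_KdCai_mult"]]
  Hi <- 10^(-m[["pH"]]) * 1e3
  nH <- ps[["serca_nH"]]
  phiCai <- (cai / ps[["serca_KdCai"]])^2
  phiCasr <- (casr / ps[["serca_KdCasr"]])^2
  phiHi <- (Hi / ps[["serca_KdHi"]])^nH
  phiHsr <- (Hi / ps[["serca_KdHsr"]])^nH
  aATP <- m[["MgATP"]] / ps[["serca_KdATP"]]
  aADP <- m[["MgADP"]] / ps[["serca_KdADP"]]
  aPi <- m[["Pi"]] / ps[["serca_KdPi"]]
  modH <- 1 / (1 + Hi / ps[["serca_KdH1"]])
  Dcyt <- 1 + phiHi + phiCai * (1 + aATP)
  Dsr <- 1 + phiHsr + phiCasr * (1 + aADP)
  ap1 <- ps[["serca_k1p"]] * phiCai * aATP / Dcyt
  ap2 <- ps[["serca_k2p"]] * phiHsr * modH / Dsr
  am1 <- ps[["serca_k1m"]] * phiCasr * aADP / Dsr
  am2 <- serca_k2m(ps) * phiHi * aPi * modH / Dcyt
  denom <- ap1 + ap2 + am1 + am2
  v_cle <- if (denom > 0) (ap1 * ap2 - am1 * am2) / denom else 0
  psp <- if (denom > 0) (ap1 + am2) / denom else NA_real_
  i_up <- ps[["serca_S"]] * v_cle * m[["sc_Iup"]]

  ## --- RyR release, leak ----------------------------------------------------
  c_uM <- cai * 1000
  sr_sens <- 1 - 1 / (1 + exp((casr - p[["RyR_srmid"]]) / p[["RyR_srk"]]))
  a_inf <- p[["RyR_amin"]] + p[["RyR_aamp"]] /
    (1 + exp(-(c_uM - p[["RyR_ac"]]) / p[["RyR_ak"]]))
  o_inf <- 1 / (1 + exp(-(c_uM - (y[["RyR_a"]] + p[["RyR_ohalf"]])) /
                        p[["RyR_ok"]]))
  c_inf <- 1 / (1 + exp((c_uM - (y[["RyR_a"]] + p[["RyR_chalf"]])) /
                        p[["RyR_ck"]]))
  i_rel <- p[["g_irel"]] * m[["sc_girel"]] * sr_sens *
    y[["RyR_o"]] * y[["RyR_c"]] * (casr - cai)
  i_leak <- p[["V_leak"]] * m[["sc_leak"]] * (casr - cai)

  ## --- contractile element ---------------------------------------------------
  ce <- cdx_ce_derivatives(
    y[ce_state_names], Ca_i = cai,
    metabolites = list(MgATP = m[["MgATP"]], MgADP = m[["MgADP"]],
                       Pi = m[["Pi"]], pH = m[["pH"]]),
    kon_scale = m[["kon_scale"]], params = p)

  ## --- balances ----------------------------------------------------------------
  gamma_chg <- p[["Cm"]] / (p[["Frdy"]] * p[["V_c"]] * 1e-18)
  bufc <- 1 / (1 + p[["Buf_C"]] * p[["Kbuf_C"]] / (cai + p[["Kbuf_C"]])^2)
  bufsr <- 1 / (1 + p[["Buf_SR"]] * p[["Kbuf_SR"]] / (casr + p[["Kbuf_SR"]])^2)
  dCai <- bufc * (i_leak - i_up + i_rel - ce$J_trpn -
                  (i_CaL + i_bCa + i_pCa - 2 * i_NCX) * gamma_chg / 2)
  dCaSR <- bufsr * (p[["V_c"]] / p[["V_SR"]]) * (i_up - i_rel - i_leak)
  dNai <- -(i_Na + i_NaL + i_bNa + 3 * i_NaK + 3 * i_NCX + i_fNa) * gamma_chg

  dO2 <- cdx_o2_derivative(y[["O2_e"]], m[["O2_s"]], i_NaK, i_pCa,
                           ce$ATPase, p)

  i_total <- i_Na + i_NaL + i_CaL + i_Kr + i_Ks + i_K1 + i_f + i_to +
    i_NaK + i_NCX + i_pCa + i_bNa + i_bCa + i_KATP

  dy <- numeric(33)
  names(dy) <- cdx_state_names()
  dy[["V"]] <- -i_total
  dy[["Ca_SR"]] <- dCaSR
  dy[["Ca_i"]] <- dCai
  dy[["Na_i"]] <- dNai
  dy[["m"]] <- (m_inf - y[["m"]]) / tau_m
  dy[["h"]] <- (h_inf - y[["h"]]) / tau_h
  dy[["j"]] <- (j_inf - y[["j"]]) / tau_j
  dy[["mL"]] <- (mL_inf - y[["mL"]]) / tau_mL
  dy[["hL"]] <- (hL_inf - y[["hL"]]) / tau_hL
  dy[["d"]] <- (d_inf - y[["d"]]) / tau_d
  dy[["f1"]] <- (f1_inf - y[["f1"]]) / tau_f1
  dy[["f2"]] <- (f2_inf - y[["f2"]]) / tau_f2
  dy[["fCa"]] <- constfCa * (fCa_inf - y[["fCa"]]) / tau_fCa
  dy[["Xr1"]] <- (Xr1_inf - y[["Xr1"]]) / tau_Xr1
  dy[["Xr2"]] <- (Xr2_inf - y[["Xr2"]]) / tau_Xr2
  dy[["Xs"]] <- (Xs_inf - y[["Xs"]]) / tau_Xs
  dy[["Xf"]] <- (Xf_inf - y[["Xf"]]) / tau_Xf
  dy[["q"]] <- (q_inf - y[["q"]]) / tau_q
  dy[["r"]] <- (r_inf - y[["r"]]) / tau_r
  dy[["RyR_a"]] <- (a_inf - y[["RyR_a"]]) / p[["RyR_tauadapt"]]
  dy[["RyR_o"]] <- (o_inf - y[["RyR_o"]]) / p[["RyR_tauact"]]
  dy[["RyR_c"]] <- (c_inf - y[["RyR_c"]]) / p[["RyR_tauinact"]]
  dy[ce_state_names] <- ce$deriv[ce_state_names]
  dy[["O2_e"]] <- dO2

  out <- c(I_Na = i_Na, I_NaL = i_NaL, I_CaL = i_CaL, I_Kr = i_Kr,
           I_Ks = i_Ks, I_K1 = i_K1, I_f = i_f, I_to = i_to,
           I_NaK = i_NaK, I_NCX = i_NCX, I_pCa = i_pCa, I_bNa = i_bNa,
           I_bCa = i_bCa, I_KATP = i_KATP, I_rel = i_rel, I_up = i_up,
           I_leak = i_leak, tension = ce$tension, ATPase = ce$ATPase,
           shortening = ce$shortening, OCR = dO2, rho = rho_o2,
           f_KATP = fk, v_cle = v_cle, PSP = psp, J_trpn = ce$J_trpn)
  list(dy = dy, out = out)
}

validate_state <- function(y) {
  nm <- cdx_state_names()
  if (length(y) != 33)
    rlang::abort(sprintf("state vector must have 33 entries, got %d", length(y)))
  if (is.null(names(y))) names(y) <- nm
  bad <- !is.finite(y)
  if (any(bad))
    rlang::abort(paste0("non-finite state entries: ",
                        paste(names(y)[bad], collapse = ", ")))
  y
}

#' Time derivative of the full 33-state model
#'
#' Pure function: the same `(t, y, env)` always returns the same derivative.
#' With the identity environment and the calibrated SERCA scale, the control
#' model beats spontaneously (no stimulus current exists in the model).
#'
#' @param t time (s); the autonomous dynamics do not depend on it directly,
#'   but protocol schedules resolve their environment at `t`.
#' @param y named state vector of length 33 (see [cdx_state_names()]).
#' @param params model parameters.
#' @param mods modifier bundle ([cdx_modifiers()]) or a function of `t`
#'   returning one (a protocol schedule).
#' @return Named derivative vector d(y)/dt.
#' @export
cdx_derivatives <- function(t, y, params = cdx_parameters(),
                            mods = cdx_modifiers(params)) {
  y <- validate_state(y)
  m <- if (is.function(mods)) mods(t) else mods
  rhs_core_r(t, y, params, m)$dy
}

#' Instantaneous currents, fluxes and couplings at a state
#'
#' The exact quantities used inside [cdx_derivatives()] (same code path),
#' exposed for logging and biomarker work: sarcolemmal currents (A/F), SR
#' fluxes (mM/s), tension (kPa), ATPase (mM/s), OCR (mM/s), the oxygen
#' coupling `rho`, the K_ATP open fraction, the SERCA cycling rate and
#' phosphorylation fraction, and the myofilament Ca2+ flux.
#'
#' @inheritParams cdx_derivatives
#' @return One-row tibble with one column per quantity.
#' @export
cdx_compute_currents <- function(y, params = cdx_parameters(),
                                 mods = cdx_modifiers(params), t = 0) {
  y <- validate_state(y)
  m <- if (is.function(mods)) mods(t) else mods
  tibble::as_tibble(as.list(rhs_core_r(t, y, params, m)$out))
}
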