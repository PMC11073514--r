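# Model parameter set and the frozen 33-state layout.
#
# Units are SI seconds and volts internally (Paci-model convention);
# concentrations in mM, currents in A/F, SR fluxes in mM/s.

#' Names and order of the 33 dynamical states
#'
#' The state layout is frozen: 22 electrophysiology states (membrane
#' potential, ionic gates, intracellular Na+, cytosolic and SR Ca2+, ryanodine
#' receptor gates), 10 contractile-element states (troponin, thin-filament
#' regulatory units, strongly bound crossbridges and their mean strains,
#' sarcomere length, super-relaxed myosin fraction) and the pericellular
#' oxygen concentration.
#'
#' @return Character vector of length 33 with the canonical state names.
#' @export
#' @examples
#' length(cdx_state_names())
cdx_state_names <- function() {
  c(
    "V",        # membrane potential (V)
    "Ca_SR",    # SR Ca2+ (mM)
    "Ca_i",     # cytosolic free Ca2+ (mM)
    "Na_i",     # intracellular Na+ (mM)
    "m", "h", "j",          # I_Na gates
    "mL", "hL",             # I_NaL gates
    "d", "f1", "f2", "fCa", # I_CaL gates
    "Xr1", "Xr2",           # I_Kr gates
    "Xs",                   # I_Ks gate
    "Xf",                   # I_f gate
    "q", "r",               # I_to gates
    "RyR_a", "RyR_o", "RyR_c", # ryanodine receptor adaptation/open/inactivation
    "trpn_T", "trpn_TCa",   # troponin: free / Ca2+-bound (sum 1)
    "xb_N", "xb_P", "xb_A", "xb_B", # tropomyosin & crossbridge occupancies (sum 1)
    "x_A", "x_B",           # mean crossbridge strains (um)
    "SL",                   # sarcomere length (um)
    "myo_SRX",              # super-relaxed myosin fraction
    "O2_e"                  # pericellular O2 (mM)
  )
}

#' Full model parameter set
#'
#' Returns the flat named vector of model parameters for the control
#' condition.  Electrophysiology constants follow the Paci-family hiPSC-CM
#' formulation (SI units: volts, seconds; concentrations mM; currents A/F);
#' the SERCA block is the two-state thermodynamic pump; the `ce_` block is the
#' mean-field crossbridge contractile element; the `o2_` block is the
#' extracellular oxygen balance.  Any entry can be overridden via `...`.
#'
#' @param ... Named scalar overrides, e.g. `cdx_parameters(g_Na = 3000)`.
#' @return Named numeric vector.
#' @export
#' @examples
#' p <- cdx_parameters()
#' p[["o2_epsilon"]]
cdx_parameters <- function(...) {
  p <- c(
    ## physical constants
    R_gas = 8.314472,        # J/(mol K)
    Temp  = 310,             # K
    Frdy  = 96485.3415,      # C/mol
    Cm    = 9.87109e-11,     # F
    V_c   = 8800,            # um^3 cytosol
    V_SR  = 583.73,          # um^3 SR

    ## external milieu (control); K_o is protocol-driven
    Na_o = 151, Ca_o = 1.8, K_o = 5, K_i = 150,

    ## maximal conductances / fluxes (Paci-family magnitudes, control)
    g_Na  = 2230,       # S/F
    g_NaL = 8,          # S/F
    g_CaL = 8.635702e-5,# m^3/(F s)
    g_Kr  = 41.8134,    # S/F
    g_Ks  = 2.041,      # S/F
    g_K1  = 28.1492,    # S/F
    g_f   = 30.10312,   # S/F
    g_to  = 29.9038,    # S/F
    P_NaK = 2.6,        # A/F
    k_NCX = 2679.51,    # A/F
    g_pCa = 0.4125,     # A/F
    g_bNa = 0.95,       # S/F
    g_bCa = 0.727272,   # S/F
    ## NCX constants
    ncx_alpha = 2.8571432, ncx_gamma = 0.38, ncx_KmCa = 1.38,
    ncx_KmNai = 87.5, ncx_Ksat = 0.1, KpCa = 5e-4,
    PkNa = 0.03,

    ## SR handling
    VmaxUp = 0.90,      # mM/s (legacy saturating uptake, used for S calibration)
    Kup    = 2.5e-4,    # mM
    V_leak = 1.5e-3,    # 1/s
    g_irel = 30,        # mM/s RyR release scale
    ## RyR gating operates on cytosolic Ca2+ in uM (c = 1e3 * Ca_i)
    RyR_amin = 0.03, RyR_aamp = 0.25, RyR_ac = 0.15, RyR_ak = 0.05,
    RyR_ohalf = 0.03, RyR_ok = 0.01, RyR_chalf = 0.25, RyR_ck = 0.05,
    RyR_srmid = 0.3, RyR_srk = 0.1, # SR-load sensitivity of release
    RyR_tauadapt = 0.3, RyR_tauact = 18.75e-3, RyR_tauinact = 87.5e-3,
    ## cytosolic / SR Ca2+ instantaneous buffers
    Buf_C = 0.18, Kbuf_C = 1e-3, Buf_SR = 10, Kbuf_SR = 0.3,

    ## I_f Na+ fraction
    f_Na_frac = 0.42,
    na_inact_shift = 6, # mV rightward shift of I_Na steady-state inactivation

    ## ATP-sensitive K+ current (Ferrero-lineage)
    g_KATP   = 155,     # S/F maximal conductance at f_KATP = 1
    katp_KoRef = 5.4,   # mM reference K_o
    katp_KoExp = 0.24,  # K_o exponent of the maximal conductance
    katp_Km0 = 35.8,    # uM, ATP half-inhibition offset
    katp_KmSlope = 17.9,# uM per (uM ADP)^0.256
    katp_KmExp = 0.256,
    katp_H0 = 1.3, katp_Hamp = 0.74, katp_Hslope = 0.09, # Hill coeff vs ADP (uM)

    ## two-state SERCA pump (rapid-equilibrium lumped cycle)
    serca_k1p = 300,     # 1/s  forward: phosphorylation + Ca2+ occlusion
    serca_k2p = 30,      # 1/s  forward: luminal release + dephosphorylation
    serca_k1m = 100,     # 1/s  backward of edge 1
    serca_KdCai  = 2e-3, # mM   cytosolic Ca2+ transport site
    serca_KdCasr = 1.2,  # mM   luminal Ca2+ site
    serca_KdHi   = 1.09e-4, # mM cytosol-facing proton site (K_d,Hi)
    serca_KdHsr  = 2e-6, # mM luminal proton site (K_d,Hsr; high affinity)
    serca_KdH1   = 5e-4, # mM modulatory cytosolic proton site (kinetic)
    serca_KdATP  = 0.6,  # mM MgATP
    serca_KdADP  = 0.02, # mM MgADP
    serca_KdPi   = 0.5,  # mM inorganic phosphate
    serca_nH     = 2,    # H+ countertransport stoichiometry
    serca_dGATP0 = -35600, # J/mol standard free energy of MgATP hydrolysis
    serca_S      = 0.028470, # flux scale factor (max legacy I_up / max v_cle, control)

    ## metabolites (control; protocol-driven in ischemia)
    met_MgATP = 6.8,   # mM
    met_MgADP = 0.015, # mM
    met_Pi    = 2,     # mM
    met_pH    = 7.15,  # cytosolic pH; luminal pH follows unless overridden

    ## contractile element (mean-field crossbridge cycle)
    ce_kon    = 40000, # 1/(mM s) troponin Ca2+ on-rate (K_on)
    ce_koff   = 25,    # 1/s troponin Ca2+ off-rate (no crossbridge load)
    ce_xbfb   = 4,     # crossbridge-feedback strength on troponin off-rate
    ce_knp    = 25,    # 1/s N -> P at full Ca activation
    ce_kpn    = 30,    # 1/s P -> N
    ce_perm50 = 0.33,  # TCa occupancy of half-permissiveness
    ce_nperm  = 4,     # Hill steepness of permissiveness
    ce_fapp   = 18,    # 1/s P -> XB_A attachment (scaled by DRX)
    ce_gapp   = 25,    # 1/s XB_A -> P detachment
    ce_hf     = 12,    # 1/s XB_A -> XB_B rotation
    ce_hb     = 4,     # 1/s XB_B -> XB_A reverse rotation at Pi_ref
    ce_PiRef  = 2,     # mM reference Pi for reverse rotation
    ce_gxb    = 20,    # 1/s XB_B -> P detachment (ATP consuming) at sat. MgATP
    ce_KdATP  = 0.03,  # mM MgATP saturation of detachment
    ce_KdADP  = 1.5,   # mM MgADP product inhibition of detachment
    ce_KdH    = 3e-4,  # mM H+ force depression constant
    ce_nHF    = 1,     # Hill exponent of H+ force depression
    ce_x0     = 0.007, # um power-stroke size
    ce_kstrain = 100,  # 1/s mean-strain relaxation rate
    ce_Tref   = 300,   # kPa tension scale at full duty
    ce_SL0    = 1.9,   # um slack sarcomere length
    ce_SLov   = 2.1, ce_SLw = 0.6, # overlap function centre/width
    ce_kpas   = 40,    # kPa/um passive stiffness
    ce_visc   = 6,     # kPa s/um viscous coefficient of shortening
    ce_rho_atp = 0.25, # mM crossbridge (myosin head) concentration
    ce_basal  = 0.245, # 1/s basal (non-twitch) DRX crossbridge ATP turnover
    ce_srx_on = 0.2, ce_srx_off = 0.2, # SRX <-> DRX exchange (1/s)
    ce_TrpnTot = 0.07, # mM total troponin Ca2+ sites

    ## oxygen dynamics
    o2_Omega   = 1.6,    # mM O2 per mM ATP (complete oxidation)
    o2_beta    = 0.2658, # maintenance weight on gamma-converted pump ATP use
    o2_epsilon = 5,      # 1/s diffusive exchange rate (as published)
    o2_D       = 2.5e-10,# m^2/s O2 diffusion coefficient
    o2_dx      = 10e-6,  # m cell-to-source distance
    o2_source  = 0.133,  # mM baseline [O2]_s
    rho_a = 1.215, rho_b = 0.215, rho_c = -1, rho_K = 0.15
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      rlang::abort("parameter overrides must be named")
    unknown <- setdiff(names(override), names(p))
    if (length(unknown))
      rlang::abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    p[names(override)] <- unlist(override)
  }
  p
}

#' Reference initial state (control condition)
#'
#' A quiescent-but-excitable starting point used to bootstrap the control
#' steady state.  Long control runs converge to the spontaneous-beating limit
#' cycle regardless of small changes here; steady-state initial conditions for
#' the protocols are packaged separately (see [cdx_steady_state()]).
#'
#' @return Named numeric vector of length 33.
#' @export
cdx_initial_state <- function() {
  y <- c(
    V = -0.070, Ca_SR = 0.32, Ca_i = 2e-5, Na_i = 9.2,
    m = 0.03, h = 0.75, j = 0.75,
    mL = 0.003, hL = 0.75,
    d = 0.0, f1 = 1.0, f2 = 1.0, fCa = 1.0,
    Xr1 = 0.0, Xr2 = 0.75, Xs = 0.0, Xf = 0.1,
    q = 1.0, r = 0.0,
    RyR_a = 0.3, RyR_o = 0.05, RyR_c = 0.9,
    trpn_T = 0.98, trpn_TCa = 0.02,
    xb_N = 0.97, xb_P = 0.01, xb_A = 0.01, xb_B = 0.01,
    x_A = 0, x_B = 0.007,
    SL = 1.9, myo_SRX = 0.5,
    O2_e = 0.11
  )
  stopifnot(identical(names(y), cdx_state_names()))
  y
}
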