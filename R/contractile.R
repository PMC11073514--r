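# Mean-field metabolite-sensitive contractile element (CE).
#
# Lineage: mean-field crossbridge cycling with explicit troponin Ca2+
# binding (on-rate K_on, the Ca2+-sensitizer target), a nonpermissive /
# permissive tropomyosin switch driven by Ca2+-bound troponin, and two
# strongly bound crossbridge states (pre- and post-rotation) that contribute
# to tension through their occupancy and mean strain.  Metabolite coupling:
# Pi reverses the powerstroke, MgATP is required for detachment (MgADP
# competes), cytosolic H+ depresses force.  Myosin availability is gated by a
# slow super-relaxed (SRX) <-> disordered-relaxed (DRX) pool; only DRX heads
# attach.  Detachment of the post-rotation state hydrolyses ATP, giving the
# contractile ATPase rate that feeds the oxygen balance (mM/s).

ce_state_names <- c("trpn_T", "trpn_TCa", "xb_N", "xb_P", "xb_A", "xb_B",
                    "x_A", "x_B", "SL", "myo_SRX")

#' Contractile-element state derivatives
#'
#' @param s named numeric vector with the 10 CE states (`trpn_T`, `trpn_TCa`,
#'   `xb_N`, `xb_P`, `xb_A`, `xb_B`, `x_A`, `x_B`, `SL`, `myo_SRX`).
#' @param Ca_i cytosolic free Ca2+ (mM).
#' @param metabolites list with `MgATP`, `MgADP`, `Pi` (mM) and `pH`.
#' @param kon_scale multiplicative scale on the troponin Ca2+ on-rate
#'   (> 0; 1 = drug free, > 1 for Ca2+ sensitizers).
#' @param params model parameters (`ce_*` entries).
#' @return List with `deriv` (named derivative vector), `tension` (kPa),
#'   `ATPase` (mM/s), `shortening` (% of slack length) and `J_trpn`
#'   (myofilament Ca2+ flux, mM/s, positive toward troponin).
#' @export
cdx_ce_derivatives <- function(s, Ca_i, metabolites = list(MgATP = 6.8,
                               MgADP = 0.015, Pi = 2, pH = 7.15),
                               kon_scale = 1, params = cdx_parameters()) {
  if (kon_scale <= 0) rlang::abort("kon_scale must be positive")
  p <- params
  occ <- s[c("trpn_T", "trpn_TCa", "xb_N", "xb_P", "xb_A", "xb_B")]
  if (any(occ < -1e-6) || any(occ > 1 + 1e-6))
    rlang::abort("CE occupancies outside [0,1]: integration fault")

  H_i <- 10^(-metabolites$pH) * 1e3

  ## troponin; strongly bound crossbridges slow Ca2+ release from troponin
  kon <- p[["ce_kon"]] * kon_scale
  xb_load <- s[["xb_A"]] + s[["xb_B"]]
  koff_eff <- p[["ce_koff"]] * max(0.1, 1 - p[["ce_xbfb"]] * xb_load)
  dTCa <- kon * Ca_i * s[["trpn_T"]] - koff_eff * s[["trpn_TCa"]]

  ## tropomyosin permissiveness from Ca2+-bound troponin
  n <- p[["ce_nperm"]]
  perm <- s[["trpn_TCa"]]^n / (s[["trpn_TCa"]]^n + p[["ce_perm50"]]^n)
  k_np <- p[["ce_knp"]] * perm
  k_pn <- p[["ce_kpn"]] * (1 - perm)

  ## crossbridge cycle rates with metabolite coupling
  drx <- 1 - s[["myo_SRX"]]
  f_app <- p[["ce_fapp"]] * drx
  g_app <- p[["ce_gapp"]]
  h_f <- p[["ce_hf"]]
  h_b <- p[["ce_hb"]] * metabolites$Pi / p[["ce_PiRef"]]
  g_xb <- p[["ce_gxb"]] *
    metabolites$MgATP / (metabolites$MgATP + p[["ce_KdATP"]]) /
    (1 + metabolites$MgADP / p[["ce_KdADP"]])

  N <- s[["xb_N"]]; P <- s[["xb_P"]]; A <- s[["xb_A"]]; B <- s[["xb_B"]]
  dN <- k_pn * P - k_np * N
  dP <- k_np * N - k_pn * P - f_app * P + g_app * A + g_xb * B
  dA <- f_app * P - (g_app + h_f) * A + h_b * B
  dB <- h_f * A - (h_b + g_xb) * B

  ## mechanics: force balance of active tension against a passive spring,
  ## viscous shortening; mean strains relax toward 0 (pre) / x0 (post) and
  ## feel half the sarcomere velocity
  ov <- exp(-(s[["SL"]] - p[["ce_SLov"]])^2 / (2 * p[["ce_SLw"]]^2))
  hfac <- 1 / (1 + (H_i / p[["ce_KdH"]])^p[["ce_nHF"]])
  tension <- p[["ce_Tref"]] * ov * hfac *
    (A * s[["x_A"]] + B * s[["x_B"]]) / p[["ce_x0"]]
  tension <- max(tension, 0)
  dSL <- (p[["ce_kpas"]] * (p[["ce_SL0"]] - s[["SL"]]) - tension) /
    p[["ce_visc"]]
  dxA <- 0.5 * dSL - p[["ce_kstrain"]] * s[["x_A"]]
  dxB <- 0.5 * dSL + p[["ce_kstrain"]] * (p[["ce_x0"]] - s[["x_B"]])

  dSRX <- p[["ce_srx_on"]] * (1 - s[["myo_SRX"]]) -
    p[["ce_srx_off"]] * s[["myo_SRX"]]

  ATPase <- p[["ce_rho_atp"]] * (g_xb * B + p[["ce_basal"]] * drx *
    metabolites$MgATP / (metabolites$MgATP + p[["ce_KdATP"]]))

  deriv <- c(trpn_T = -dTCa, trpn_TCa = dTCa,
             xb_N = dN, xb_P = dP, xb_A = dA, xb_B = dB,
             x_A = dxA, x_B = dxB, SL = dSL, myo_SRX = dSRX)
  list(deriv = deriv,
       tension = tension,
       ATPase = ATPase,
       shortening = 100 * (p[["ce_SL0"]] - s[["SL"]]) / p[["ce_SL0"]],
       J_trpn = p[["ce_TrpnTot"]] * dTCa)
}

#' Contractile-element outputs at a given state
#'
#' Tension (kPa), contractile ATPase rate (mM/s, the unit required by the
#' oxygen balance) and fractional cell shortening (%) without computing the
#' state derivatives.
#'
#' @inheritParams cdx_ce_derivatives
#' @return Tibble with columns `tension`, `ATPase`, `shortening`.
#' @export
cdx_ce_outputs <- function(s, metabolites = list(MgATP = 6.8, MgADP = 0.015,
                           Pi = 2, pH = 7.15), params = cdx_parameters()) {
  out <- cdx_ce_derivatives(s, Ca_i = 0, metabolites = metabolites,
                            kon_scale = 1, params = params)
  tibble::tibble(tension = out$tension, ATPase = out$ATPase,
                 shortening = out$shortening)
}

#' Steady-state troponin occupancy at fixed Ca2+
#'
#' Closed form for the isolated troponin sub-system:
#' `TCa = kon*Ca / (kon*Ca + koff)`.
#'
#' @inheritParams cdx_ce_derivatives
#' @return Equilibrium Ca2+-bound troponin fraction.
#' @export
cdx_trpn_steady <- function(Ca_i, kon_scale = 1, params = cdx_parameters()) {
  kon <- params[["ce_kon"]] * kon_scale
  kon * Ca_i / (kon * Ca_i + params[["ce_koff"]])
}
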