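# ATP-sensitive K+ current (Ferrero-lineage formulation).
#
# The fraction of open K_ATP channels is a Hill function of intracellular
# MgATP whose half-inhibition constant and Hill coefficient are themselves
# functions of MgADP; the current is an outward K+ current whose maximal
# conductance scales with (K_o / K_o,ref)^0.24.

#' Open fraction of ATP-sensitive K+ channels
#'
#' `f_KATP = 1 / (1 + (MgATP/Km)^H)` with `Km = Km0 + KmSlope * ADP_uM^KmExp`
#' (micromolar) and `H = H0 + Hamp * exp(-Hslope * ADP_uM)`.  Strictly
#' decreasing in MgATP, increasing in MgADP.
#'
#' @param MgATP,MgADP intracellular Mg-nucleotide concentrations (mM).
#' @param params model parameters; uses the `katp_*` entries.
#' @return Open fraction in `[0, 1]` (vectorized).
#' @export
#' @examples
#' cdx_f_katp(6.8, 0.015)            # control: channels essentially shut
#' cdx_f_katp(4.6, 0.099)            # severe ischemia: larger open fraction
cdx_f_katp <- function(MgATP, MgADP, params = cdx_parameters()) {
  if (any(MgATP < 0) || any(MgADP < 0))
    rlang::abort("nucleotide concentrations must be non-negative")
  p <- params
  atp_uM <- MgATP * 1e3
  adp_uM <- MgADP * 1e3
  Km <- p[["katp_Km0"]] + p[["katp_KmSlope"]] * adp_uM^p[["katp_KmExp"]]
  H <- p[["katp_H0"]] + p[["katp_Hamp"]] * exp(-p[["katp_Hslope"]] * adp_uM)
  1 / (1 + (atp_uM / Km)^H)
}

#' ATP-sensitive K+ current
#'
#' `I_KATP = g_KATP * (K_o/K_o,ref)^0.24 * f * drug_scale * (V - E_K)` (A/F).
#' `f` is the nucleotide-dependent open fraction ([cdx_f_katp()]), optionally
#' amplified by a channel-opener drug scale (levosimendan pathway).
#'
#' @param V membrane potential (volts).
#' @param K_o extracellular K+ (mM).
#' @param f open fraction in `[0, 1]`.
#' @param drug_scale multiplicative opener scale (>= 1 for activators; 1 = no
#'   drug).
#' @param params model parameters.
#' @param Na_i intracellular Na+ (mM), unused but kept for signature parity
#'   with other current helpers.
#' @return Current in A/F (vectorized).
#' @export
cdx_i_katp <- function(V, K_o, f, drug_scale = 1, params = cdx_parameters(),
                       Na_i = NULL) {
  if (any(f < 0) || any(f > 1))
    rlang::abort("open fraction f must lie in [0, 1]")
  if (any(drug_scale < 0))
    rlang::abort("drug_scale must be non-negative")
  p <- params
  RT_F <- p[["R_gas"]] * p[["Temp"]] / p[["Frdy"]]
  EK <- RT_F * log(K_o / p[["K_i"]])
  p[["g_KATP"]] * (K_o / p[["katp_KoRef"]])^p[["katp_KoExp"]] *
    f * drug_scale * (V - EK)
}
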