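# Extracellular oxygen balance and its feedback on the ATP-driven pumps.
#
# Pericellular O2 ([O2]_e, state 33) relaxes diffusively toward the source
# (capillary/bath) concentration [O2]_s and is consumed by ATP turnover:
# the gamma-converted Na+/K+ and sarcolemmal Ca2+ pump currents (weighted by
# the maintenance factor beta) plus the contractile ATPase rate, all scaled by
# Omega mM O2 per mM ATP.  Source oxygen feeds back on the pumps through the
# ouabain-like sigmoid rho: f_NaK = f_pCa = rho([O2]_s).

#' Charge-utilization factor gamma
#'
#' Converts a sarcolemmal pump current density (A/F) to an ATP consumption
#' rate (mM/s): `gamma = Cm / (F * Vc)` with the cell capacitance in farad,
#' the Faraday constant in C/mol and the cytosolic volume in m^3.  Current *
#' Cm gives amperes; dividing by F yields mol/s of elementary charge turnover;
#' dividing by the volume yields mol/(m^3 s) = mM/s.
#'
#' @param C_m cell capacitance (F).
#' @param F_const Faraday constant (C/mol).
#' @param V_c cell volume (m^3).
#' @return gamma in mM/s per A/F.
#' @export
#' @examples
#' cdx_gamma_factor() # ~0.1163
cdx_gamma_factor <- function(C_m = 98.7109e-12, F_const = 96485.3415,
                             V_c = 8800e-18) {
  C_m / (F_const * V_c)
}

#' Diffusive oxygen exchange rate
#'
#' Fick-law rate constant for the source-to-pericellular O2 exchange:
#' `epsilon = geometry * D / dx^2` (1/s).  With the packaged diffusion
#' coefficient and inter-cell distance the bare ratio `D/dx^2` is 2.5 1/s;
#' the packaged default uses a two-sided planar exchange factor of 2, giving
#' the 5 1/s used in all protocols (both the factor and epsilon itself are
#' configurable; see the methods vignette for the discrepancy discussion).
#'
#' @param D O2 diffusion coefficient (m^2/s).
#' @param dx diffusion distance (m).
#' @param geometry geometric factor (default 2).
#' @return epsilon in 1/s.
#' @export
#' @examples
#' cdx_diffusion_rate()                 # 5
#' cdx_diffusion_rate(geometry = 1)     # bare Fick ratio: 2.5
cdx_diffusion_rate <- function(D = 2.5e-10, dx = 10e-6, geometry = 2) {
  if (D <= 0 || dx <= 0) rlang::abort("D and dx must be positive")
  geometry * D / dx^2
}

#' Ouabain-like oxygen-to-pump coupling rho
#'
#' Normalized Na+/K+-ATPase (and sarcolemmal Ca2+ pump) activity as a
#' function of source oxygen.  The raw curve is the c = -1 Hill (Michaelis)
#' form `rho_raw(x) = (a*x + b*K) / (x + K)` on oxygen normalized to the
#' baseline source concentration (`x = O2_s / 0.133 mM`), with half constant
#' `K = 0.15` (the curve IC50 sits at 15% of the maximum concentration, the
#' ouabain dose-response analogy).  Pump scalings use the curve normalized to
#' 1 at baseline oxygen, so the control condition is the identity:
#' `rho = rho_raw(x) / rho_raw(1)`.
#'
#' @param O2_s source oxygen concentration (mM), >= 0.
#' @param params model parameters (`rho_a`, `rho_b`, `rho_c`, `rho_K`,
#'   `o2_source`).
#' @param normalize if `TRUE` (default) normalize to 1 at the baseline source
#'   concentration; `FALSE` returns the raw curve.
#' @return Normalized pump activity (vectorized, monotone increasing).
#' @export
#' @examples
#' cdx_rho(0.133)    # 1 at baseline
#' cdx_rho(0.03745)  # ~0.80: the SEV1 setting (20% pump inhibition)
cdx_rho <- function(O2_s, params = cdx_parameters(), normalize = TRUE) {
  if (any(O2_s < 0)) rlang::abort("O2_s must be non-negative")
  p <- params
  a <- p[["rho_a"]]; b <- p[["rho_b"]]; K <- p[["rho_K"]]
  cc <- p[["rho_c"]]
  x <- O2_s / p[["o2_source"]]
  # (a*x + b*K)/(x + K) is the c = -1 member of a + (b - a)/(1 + (x/K)^-c)
  raw <- a + (b - a) / (1 + (x / K)^(-cc))
  if (!normalize) return(raw)
  base <- a + (b - a) / (1 + (1 / K)^(-cc))
  raw / base
}

#' Source-oxygen level producing a target pump activity
#'
#' Inverts [cdx_rho()]: returns the `[O2]_s` at which the normalized pump
#' activity equals `rho_target`.  Used to construct the ischemic severity
#' settings (20% and 31% Na+/K+ pump inhibition).
#'
#' @param rho_target normalized activity in (0, 1].
#' @param params model parameters.
#' @return `[O2]_s` in mM.
#' @export
#' @examples
#' cdx_o2s_for_rho(0.80) # SEV1 source oxygen
cdx_o2s_for_rho <- function(rho_target, params = cdx_parameters()) {
  p <- params
  a <- p[["rho_a"]]; b <- p[["rho_b"]]; K <- p[["rho_K"]]
  base <- (a + b * K) / (1 + K)
  raw <- rho_target * base
  if (any(raw <= b) || any(raw >= a))
    rlang::abort("rho_target outside the attainable range of the curve")
  x <- K * (raw - b) / (a - raw)
  x * p[["o2_source"]]
}

#' Time derivative of pericellular oxygen
#'
#' `d[O2]_e/dt = epsilon*([O2]_s - [O2]_e) -
#'               Omega*(beta*gamma*(I_NaK + I_pCa) + ATPase)`
#' (mM/s).  The pump-current term is the cell-maintenance share of ATP
#' turnover (converted from A/F by gamma and weighted by beta = 0.2658 so the
#' steady control split is ~79% contraction / 21% maintenance); the
#' contractile ATPase enters directly in mM/s.  Its negative is reported as
#' the oxygen consumption rate (OCR).
#'
#' @param O2_e pericellular oxygen (mM).
#' @param O2_s source oxygen (mM).
#' @param I_NaK,I_pCa pump current magnitudes (A/F).
#' @param ATPase contractile ATPase rate (mM/s).
#' @param params model parameters.
#' @return d[O2]_e/dt in mM/s.
#' @export
cdx_o2_derivative <- function(O2_e, O2_s, I_NaK, I_pCa, ATPase,
                              params = cdx_parameters()) {
  p <- params
  gamma <- cdx_gamma_factor(p[["Cm"]], p[["Frdy"]], p[["V_c"]] * 1e-18)
  p[["o2_epsilon"]] * (O2_s - O2_e) -
    p[["o2_Omega"]] * (p[["o2_beta"]] * gamma * (I_NaK + I_pCa) + ATPase)
}
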