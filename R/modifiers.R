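# Environment / drug modifier bundle.
#
# A Modifiers vector carries everything a protocol or drug can change at run
# time without touching the base parameter set: multiplicative scales on
# maximal conductances and fluxes, the extracellular environment (K_o, source
# oxygen, metabolites, pH), the SERCA ischemic recalibration multipliers and
# the drug hooks (troponin K_on scale, K_ATP opener scale, direct f_NaK /
# f_pCa overrides).  The default instance is the identity: all scales 1 and
# the control environment.

mod_scale_names <- c("sc_gNa", "sc_gNaL", "sc_gCaL", "sc_gKr", "sc_gKs",
                     "sc_gK1", "sc_gf", "sc_gto", "sc_PNaK", "sc_kNCX",
                     "sc_gpCa", "sc_gbNa", "sc_gbCa", "sc_gKATP", "sc_girel",
                     "sc_Iup", "sc_leak")
mod_serca_names <- c("serca_k1p_mult", "serca_k2p_mult", "serca_KdHsr_mult",
                     "serca_KdPi_mult", "serca_KdCai_mult")
mod_env_names <- c("K_o", "O2_s", "MgATP", "MgADP", "Pi", "pH")
mod_drug_names <- c("kon_scale", "fkatp_scale", "f_NaK", "f_pCa")

#' Construct a modifier bundle
#'
#' @param params model parameters supplying the control environment defaults.
#' @param ... named overrides: conductance scales (`sc_gNa`, `sc_gCaL`,
#'   `sc_gKr`, `sc_gKs`, `sc_gK1`, `sc_gf`, `sc_gto`, `sc_PNaK`, `sc_kNCX`,
#'   `sc_gpCa`, `sc_gbNa`, `sc_gbCa`, `sc_gKATP`, `sc_girel`, `sc_Iup`,
#'   `sc_leak`), SERCA recalibration multipliers (`serca_k1p_mult`,
#'   `serca_KdHsr_mult`, `serca_KdPi_mult`, `serca_KdCai_mult`), environment (`K_o`, `O2_s`,
#'   `MgATP`, `MgADP`, `Pi`, `pH`) and drug hooks (`kon_scale`,
#'   `fkatp_scale`, `f_NaK`, `f_pCa`; the latter two multiply the
#'   oxygen-derived rho coupling and default to 1).
#' @return Named numeric modifier vector.
#' @export
#' @examples
#' cdx_modifiers()                 # identity / control
#' cdx_modifiers(sc_gKr = 0.15)    # 85% I_Kr block
cdx_modifiers <- function(params = cdx_parameters(), ...) {
  m <- c(
    setNames(rep(1, length(mod_scale_names)), mod_scale_names),
    setNames(rep(1, length(mod_serca_names)), mod_serca_names),
    K_o = params[["K_o"]], O2_s = params[["o2_source"]],
    MgATP = params[["met_MgATP"]], MgADP = params[["met_MgADP"]],
    Pi = params[["met_Pi"]], pH = params[["met_pH"]],
    kon_scale = 1, fkatp_scale = 1, f_NaK = 1, f_pCa = 1
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      rlang::abort("modifier overrides must be named")
    unknown <- setdiff(names(override), names(m))
    if (length(unknown))
      rlang::abort(paste0("unknown modifier(s): ", paste(unknown, collapse = ", ")))
    m[names(override)] <- unlist(override)
  }
  sc <- m[c(mod_scale_names, mod_serca_names, mod_drug_names)]
  if (any(sc < 0)) rlang::abort("modifier scales must be non-negative")
  m
}

# merge two modifier bundles: scales multiply, environment entries are taken
# from `b` where they differ from the identity environment in `a0`
mod_combine <- function(a, b) {
  out <- a
  mult <- c(mod_scale_names, mod_serca_names, mod_drug_names)
  out[mult] <- a[mult] * b[mult]
  out
}
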