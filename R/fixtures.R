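# Synthetic trace fixtures with closed-form ground truth, used to validate
# the biomarker extractors independently of the ODE model.

#' Generate a synthetic analysis fixture
#'
#' Analytic traces whose biomarker values are known exactly:
#'
#' * `"ap_train"`: periodic triangular action potentials (linear upstroke and
#'   repolarization).  Ground truth: beat rate `1/period`; APD_x from the
#'   descending-limb geometry, e.g. `APD90 = t_up + 0.9 * t_down` measured
#'   from the upstroke foot.
#' * `"cat_exp"`: repeated calcium transients with instantaneous rise and
#'   single-exponential decay at rate `k`; `tDecay90,10 = log(9)/k`.
#' * `"twitch"`: smooth tension twitches, optionally with an injected
#'   diastolic bump (one aftercontraction per beat).
#' * `"ap_ead"`: triangular AP train with an optional depolarizing hump
#'   injected during repolarization (one EAD per beat).
#'
#' @param kind fixture type.
#' @param period beat period (s).
#' @param n_beats number of beats.
#' @param dt sample interval (s).
#' @param amp amplitude: volts for AP traces, mM for Ca, kPa for tension.
#' @param baseline resting level (same units).
#' @param k exponential decay rate (1/s), `"cat_exp"` only.
#' @param t_up,t_down upstroke / repolarization durations (s), AP kinds.
#' @param bump logical: inject the abnormality (`"twitch"`, `"ap_ead"`).
#' @param noise_sd Gaussian noise SD added to the signal (0 = none).
#' @param seed RNG seed used when `noise_sd > 0` (byte-identical regeneration
#'   for a fixed seed).
#' @return Tibble with `time` plus the signal column (`V`, `Ca_i` or
#'   `tension`); ground-truth values in `attr(, "truth")`.
#' @export
#' @examples
#' fx <- cdx_make_fixture("cat_exp", k = 10)
#' attr(fx, "truth")$tDecay9010_ms # log(9)/10 * 1000
cdx_make_fixture <- function(kind = c("ap_train", "cat_exp", "twitch",
                                      "ap_ead"),
                             period = 1.25, n_beats = 12, dt = 1e-3,
                             amp = NULL, baseline = NULL, k = 10,
                             t_up = 0.01, t_down = 0.35, bump = FALSE,
                             noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  tt <- seq(0, n_beats * period, by = dt)
  ph <- tt %% period
  truth <- list(rate_Hz = 1 / period, n_beats = n_beats)

  if (kind %in% c("ap_train", "ap_ead")) {
    amp <- amp %||% 0.11
    baseline <- baseline %||% -0.08
    v <- ifelse(ph < t_up, baseline + amp * ph / t_up,
         ifelse(ph < t_up + t_down,
                baseline + amp * (1 - (ph - t_up) / t_down), baseline))
    if (kind == "ap_ead" && bump) {
      # depolarizing hump centred mid-repolarization
      bc <- t_up + 0.5 * t_down
      v <- v + 0.25 * amp * exp(-((ph - bc) / (0.08 * t_down))^2)
      truth$EAD_per_beat <- 1L
    } else truth$EAD_per_beat <- 0L
    truth$APD90_ms <- (t_up + 0.9 * t_down) * 1000
    truth$APD50_ms <- (t_up + 0.5 * t_down) * 1000
    truth$APD30_ms <- (t_up + 0.3 * t_down) * 1000
    truth$dVdt_max <- amp / t_up
    truth$MDP_mV <- baseline * 1000
    sig <- v; cn <- "V"
  } else if (kind == "cat_exp") {
    amp <- amp %||% 3e-4
    baseline <- baseline %||% 5e-5
    # the transient peaks shortly after the (auxiliary) upstroke so the
    # pre-upstroke sample is a true diastolic baseline
    lag <- 0.02
    phc <- (ph - lag) %% period
    sig <- baseline + amp * exp(-k * phc)
    truth$tDecay9010_ms <- log(9) / k * 1000
    truth$CaT_amp_mM <- amp
    truth$CaT_base_mM <- baseline
    cn <- "Ca_i"
  } else { # twitch
    amp <- amp %||% 3
    baseline <- baseline %||% 0.05
    tau1 <- 0.05; tau2 <- 0.12
    lagt <- 0.02
    pht <- (ph - lagt) %% period
    shape <- (exp(-pht / tau2) - exp(-pht / tau1))
    shape <- shape / max(shape)
    sig <- baseline + amp * shape
    if (bump) {
      bc <- 0.65 * period
      sig <- sig + 0.25 * amp * exp(-((pht - bc) / 0.04)^2)
      truth$aftercontractions_per_beat <- 1L
    } else truth$aftercontractions_per_beat <- 0L
    truth$tension_peak <- baseline + amp
    cn <- "tension"
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
  }
  out <- tibble::tibble(time = tt)
  out[[cn]] <- sig
  # AP fixtures need a V column for segmentation even for Ca/tension kinds:
  if (cn != "V") {
    vph <- ifelse(ph < t_up, -0.08 + 0.11 * ph / t_up,
           ifelse(ph < t_up + t_down,
                  -0.08 + 0.11 * (1 - (ph - t_up) / t_down), -0.08))
    out$V <- vph
  }
  structure(out, truth = truth)
}
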