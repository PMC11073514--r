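# Beat segmentation and biomarker quantification.
#
# All threshold-crossing metrics are computed on a uniform 1 ms grid obtained
# by linear interpolation of the solver output (threshold metrics are
# sampling-sensitive; the grid is fixed so results do not depend on the
# solver's internal steps).  Sign convention for the Na+/Ca2+ exchanger:
# positive I_NCX is reverse mode (Ca2+ influx), matching the exchanger
# equation in the model core; the reverse-mode mask is therefore
# `I_NCX > 0`.

#' Segment a trace into spontaneous beats
#'
#' Beats are delimited at upstroke times: local maxima of dV/dt exceeding
#' `frac_up` of the trace-wide maximum upstroke velocity, separated by at
#' least `min_sep` seconds and taking off from below `v_gate`.  A quiescent
#' trace yields zero beats (a result, not an error).
#'
#' @param trace tibble with at least `time` and `V` (volts); other columns
#'   are carried onto the 1 ms grid.
#' @param window optional `c(start, end)` restriction (s).
#' @param dt resampling interval (s), default 1 ms.
#' @param frac_up upstroke threshold as a fraction of the maximum dV/dt.
#' @param min_sep minimum beat separation (s).
#' @param v_gate take-off gate: the membrane potential just before an
#'   upstroke must be below this (volts).
#' @return A `cardiox_beats` object: list with `grid` (uniform-grid tibble
#'   including `dVdt` in V/s) and `beats` (tibble: `beat`, `t_up`, `t_end`).
#' @export
cdx_segment_beats <- function(trace, window = NULL, dt = 1e-3,
                              frac_up = 0.25, min_sep = 0.3,
                              v_gate = -0.04) {
  stopifnot(all(c("time", "V") %in% names(trace)))
  tt <- trace$time
  if (is.unsorted(tt, strictly = TRUE)) rlang::abort("time must be strictly increasing")
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    trace <- trace[keep, ]
    tt <- trace$time
  }
  grid_t <- seq(min(tt), max(tt), by = dt)
  num_cols <- names(trace)[vapply(trace, is.numeric, TRUE)]
  grid <- tibble::as_tibble(lapply(
    setNames(num_cols, num_cols),
    function(cn) approx(tt, trace[[cn]], xout = grid_t, ties = "ordered")$y))
  grid$time <- grid_t
  dV <- c(NA_real_, diff(grid$V)) / dt
  grid$dVdt <- dV

  up_max <- max(dV, na.rm = TRUE)
  beats <- tibble::tibble(beat = integer(), t_up = numeric(),
                          t_end = numeric())
  if (is.finite(up_max) && up_max > 1) { # < 1 V/s everywhere: quiescent
    thr <- frac_up * up_max
    cand <- which(dV >= thr)
    cand <- cand[grid$V[pmax(cand - 10L, 1L)] < v_gate]
    ups <- numeric(0)
    for (i in cand) {
      ti <- grid_t[i]
      if (!length(ups) || ti - ups[length(ups)] >= min_sep) ups <- c(ups, ti)
      else if (dV[i] > dV[match(ups[length(ups)], grid_t)])
        ups[length(ups)] <- ti
    }
    if (length(ups) >= 2) {
      beats <- tibble::tibble(
        beat = seq_len(length(ups) - 1),
        t_up = ups[-length(ups)],
        t_end = ups[-1])
    }
  }
  structure(list(grid = grid, beats = beats), class = "cardiox_beats")
}

#' @export
print.cardiox_beats <- function(x, ...) {
  cat("<cardiox_beats>", nrow(x$beats), "beats on",
      nrow(x$grid), "grid points\n")
  invisible(x)
}

beat_slice <- function(seg, i) {
  b <- seg$beats[i, ]
  seg$grid[seg$grid$time >= b$t_up & seg$grid$time < b$t_end, ]
}

last_beats <- function(seg, last_n) {
  n <- nrow(seg$beats)
  if (n == 0) return(integer(0))
  seq.int(max(1L, n - last_n + 1L), n)
}

#' Action-potential metrics
#'
#' Per-beat APD30/50/90 (ms; from the upstroke to the final crossing of the
#' threshold `peak - x% * (peak - MDP)`), maximum upstroke velocity (V/s),
#' maximum diastolic potential (mV) and beat rate, averaged over the last
#' `last_n` beats.
#'
#' @param seg a `cardiox_beats` segmentation.
#' @param last_n number of final beats to average (default 10).
#' @return One-row tibble: `rate_Hz`, `dVdt_max`, `MDP_mV`, `APD30_ms`,
#'   `APD50_ms`, `APD90_ms`, `n_beats`; per-beat values in
#'   `attr(, "per_beat")`.
#' @export
cdx_ap_metrics <- function(seg, last_n = 10) {
  idx <- last_beats(seg, last_n)
  empty <- tibble::tibble(rate_Hz = NA_real_, dVdt_max = NA_real_,
                          MDP_mV = NA_real_, APD30_ms = NA_real_,
                          APD50_ms = NA_real_, APD90_ms = NA_real_,
                          n_beats = 0L)
  if (!length(idx)) return(empty)
  per <- purrr::map_dfr(idx, function(i) {
    g <- beat_slice(seg, i)
    V <- g$V * 1000
    pk_i <- which.max(V)
    mdp <- min(V)
    amp <- V[pk_i] - mdp
    apd <- function(x) {
      thr <- V[pk_i] - x / 100 * amp
      below <- which(V[-seq_len(pk_i)] <= thr) + pk_i
      if (!length(below)) return(NA_real_)
      runs <- below[c(diff(below) > 1, FALSE)]
      last_cross <- if (length(runs)) max(runs) + 1 else below[1]
      (g$time[min(last_cross, length(V))] - g$time[1]) * 1000
    }
    tibble::tibble(beat = seg$beats$beat[i],
                   dVdt_max = max(g$dVdt, na.rm = TRUE),
                   MDP_mV = mdp,
                   APD30_ms = apd(30), APD50_ms = apd(50), APD90_ms = apd(90),
                   period = g$time[nrow(g)] + 1e-3 - g$time[1])
  })
  tibble::tibble(rate_Hz = 1 / mean(per$period),
                 dVdt_max = mean(per$dVdt_max),
                 MDP_mV = mean(per$MDP_mV),
                 APD30_ms = mean(per$APD30_ms, na.rm = TRUE),
                 APD50_ms = mean(per$APD50_ms, na.rm = TRUE),
                 APD90_ms = mean(per$APD90_ms, na.rm = TRUE),
                 n_beats = length(idx)) |>
    structure(per_beat = per)
}

#' Calcium-transient metrics
#'
#' Per-beat amplitude, diastolic baseline and decay time from 90% to 10% of
#' the baseline-referenced peak on the decay limb (`tDecay90,10`), averaged
#' over the last `last_n` beats.  Double-peaked transients are measured from
#' the global beat maximum and flagged.
#'
#' @inheritParams cdx_ap_metrics
#' @return One-row tibble: `CaT_amp_mM`, `CaT_base_mM`, `tDecay9010_ms`,
#'   `CaT_abnormal` (count of flagged beats); per-beat table in
#'   `attr(, "per_beat")`.
#' @export
cdx_cat_metrics <- function(seg, last_n = 10) {
  stopifnot("Ca_i" %in% names(seg$grid))
  idx <- last_beats(seg, last_n)
  empty <- tibble::tibble(CaT_amp_mM = NA_real_, CaT_base_mM = NA_real_,
                          tDecay9010_ms = NA_real_, CaT_abnormal = 0L)
  if (!length(idx)) return(empty)
  per <- purrr::map_dfr(idx, function(i) {
    g <- beat_slice(seg, i)
    ca <- g$Ca_i
    base <- ca[1] # pre-upstroke diastolic level
    pk_i <- which.max(ca)
    amp <- ca[pk_i] - base
    dec <- ca[pk_i:length(ca)]
    td <- g$time[pk_i:length(ca)]
    i90 <- which(dec <= base + 0.9 * amp)[1]
    i10 <- which(dec <= base + 0.1 * amp)[1]
    # secondary-peak flag: any local max after the global peak above 20% amp
    sec <- FALSE
    if (length(dec) > 2) {
      lm <- which(diff(sign(diff(dec))) == -2) + 1
      sec <- any(dec[lm] > base + 0.2 * amp & lm > i90[1] %||% 1)
    }
    tibble::tibble(beat = seg$beats$beat[i], amp = amp, base = base,
                   tdec = if (!is.na(i90) && !is.na(i10))
                     (td[i10] - td[i90]) * 1000 else NA_real_,
                   abnormal = isTRUE(sec))
  })
  tibble::tibble(CaT_amp_mM = mean(per$amp),
                 CaT_base_mM = mean(per$base),
                 tDecay9010_ms = mean(per$tdec, na.rm = TRUE),
                 CaT_abnormal = sum(per$abnormal)) |>
    structure(per_beat = per)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || is.na(a[1])) b else a

#' Per-beat reverse-mode NCX integral
#'
#' Integrates the reverse-mode (Ca2+-influx, `I_NCX > 0`) portion of the
#' exchanger current over each beat (trapezoidal rule on the 1 ms grid) and
#' averages the last `last_n` beats.  Units: A/F * s (charge-equivalent area
#' per unit capacitance).
#'
#' @inheritParams cdx_ap_metrics
#' @return One-row tibble: `ncx_reverse_area`, `n_beats`.
#' @export
cdx_ncx_reverse_integral <- function(seg, last_n = 10) {
  stopifnot("I_NCX" %in% names(seg$grid))
  idx <- last_beats(seg, last_n)
  if (!length(idx))
    return(tibble::tibble(ncx_reverse_area = NA_real_, n_beats = 0L))
  areas <- vapply(idx, function(i) {
    g <- beat_slice(seg, i)
    x <- pmax(g$I_NCX, 0)
    sum((x[-1] + x[-length(x)]) / 2 * diff(g$time))
  }, 0)
  tibble::tibble(ncx_reverse_area = mean(areas), n_beats = length(idx))
}

#' Detect early afterdepolarizations
#'
#' An EAD is a positive-going dV/dt excursion exceeding `dvdt_thresh` (V/s)
#' sustained for at least `persist` seconds, occurring after the AP peak and
#' before 90% repolarization of the beat.
#'
#' @inheritParams cdx_ap_metrics
#' @param dvdt_thresh dV/dt threshold (V/s).
#' @param persist minimum duration above threshold (s).
#' @param beats which beats to scan (default all).
#' @return Tibble of events: `beat`, `t_event`; zero rows if none.
#' @export
cdx_detect_ead <- function(seg, dvdt_thresh = 0.05, persist = 5e-3,
                           beats = NULL) {
  if (is.null(beats)) beats <- seq_len(nrow(seg$beats))
  empty <- tibble::tibble(beat = integer(), t_event = numeric())
  if (!length(beats) || !nrow(seg$beats)) return(empty)
  out <- purrr::map_dfr(beats, function(i) {
    g <- beat_slice(seg, i)
    V <- g$V * 1000
    pk_i <- which.max(V)
    mdp <- min(V)
    thr90 <- V[pk_i] - 0.9 * (V[pk_i] - mdp)
    # repolarization-phase mask: after peak, before final 90% crossing
    post <- seq.int(pk_i, nrow(g))
    below <- post[V[post] <= thr90]
    end_i <- if (length(below)) below[1] else nrow(g)
    mask <- seq.int(min(pk_i + 10, end_i), end_i)
    if (length(mask) < 3) return(NULL)
    hot <- g$dVdt[mask] > dvdt_thresh
    hot[is.na(hot)] <- FALSE
    r <- rle(hot)
    need <- ceiling(persist / 1e-3)
    runs <- which(r$values & r$lengths >= need)
    if (!length(runs)) return(NULL)
    starts <- cumsum(c(1, r$lengths))[runs]
    tibble::tibble(beat = seg$beats$beat[i],
                   t_event = g$time[mask[starts]])
  })
  if (!nrow(out)) empty else out
}

#' Detect aftercontractions
#'
#' Secondary tension peaks during diastole: local maxima occurring after the
#' main twitch has decayed below `diastole_frac` of its peak, with
#' prominence above `prominence` of the twitch amplitude.
#'
#' @inheritParams cdx_ap_metrics
#' @param prominence relative prominence threshold (fraction of twitch
#'   amplitude).
#' @param diastole_frac fraction of the twitch peak below which diastole is
#'   declared.
#' @param beats which beats to scan (default all).
#' @return Tibble of events: `beat`, `t_event`, `tension`.
#' @export
cdx_detect_aftercontractions <- function(seg, prominence = 0.05,
                                         diastole_frac = 0.3,
                                         beats = NULL) {
  stopifnot("tension" %in% names(seg$grid))
  if (is.null(beats)) beats <- seq_len(nrow(seg$beats))
  empty <- tibble::tibble(beat = integer(), t_event = numeric(),
                          tension = numeric())
  if (!length(beats) || !nrow(seg$beats)) return(empty)
  out <- purrr::map_dfr(beats, function(i) {
    g <- beat_slice(seg, i)
    Tn <- g$tension
    base <- min(Tn)
    pk_i <- which.max(Tn)
    amp <- Tn[pk_i] - base
    if (amp <= 0) return(NULL)
    below <- which(Tn[-seq_len(pk_i)] < base + diastole_frac * amp) + pk_i
    if (!length(below)) return(NULL)
    dia <- seq.int(below[1], nrow(g))
    if (length(dia) < 5) return(NULL)
    x <- Tn[dia]
    lm <- which(diff(sign(diff(x))) == -2) + 1
    if (!length(lm)) return(NULL)
    keep <- vapply(lm, function(k) {
      left_min <- min(x[seq_len(k)])
      (x[k] - left_min) >= prominence * amp
    }, TRUE)
    lm <- lm[keep]
    if (!length(lm)) return(NULL)
    tibble::tibble(beat = seg$beats$beat[i],
                   t_event = g$time[dia[lm]], tension = x[lm])
  })
  if (!nrow(out)) empty else out
}

#' Full biomarker report
#'
#' Quantifies a simulation (or raw trace) over an analysis window into the
#' standard report: AP metrics, CaT metrics, peak tension and fractional
#' shortening, per-beat reverse-mode NCX area, OCR amplitude, EAD and
#' aftercontraction counts and SERCA phosphorylation statistics, averaged
#' over the last `last_n` beats of the window.
#'
#' @param sim a `cardiox_sim` object, `cardiox_beats` segmentation, or raw
#'   trace tibble.
#' @param window analysis window `c(start, end)` in seconds; default the
#'   final 30 s of the trace.
#' @param last_n number of final beats for averaged metrics.
#' @return One-row tibble (the biomarker report).
#' @export
#' @examples
#' \donttest{
#' sim <- cdx_simulate("control", duration = 60)
#' cdx_biomarkers(sim)
#' }
cdx_biomarkers <- function(sim, window = NULL, last_n = 10) {
  trace <- if (inherits(sim, "cardiox_sim")) sim$trace
           else if (inherits(sim, "cardiox_beats")) NULL
           else sim
  seg <- if (inherits(sim, "cardiox_beats")) sim else {
    if (is.null(window)) {
      tmax <- max(trace$time)
      window <- c(max(min(trace$time), tmax - 30), tmax)
    }
    cdx_segment_beats(trace, window = window)
  }
  ap <- cdx_ap_metrics(seg, last_n)
  has <- function(cn) cn %in% names(seg$grid)
  cat_m <- if (has("Ca_i")) cdx_cat_metrics(seg, last_n) else NULL
  ncx <- if (has("I_NCX")) cdx_ncx_reverse_integral(seg, last_n) else NULL
  idx <- last_beats(seg, last_n)
  gsel <- if (length(idx))
    seg$grid[seg$grid$time >= seg$beats$t_up[idx[1]], ] else seg$grid
  out <- dplyr::bind_cols(
    ap,
    if (!is.null(cat_m)) cat_m,
    if (!is.null(ncx)) ncx[, "ncx_reverse_area"],
    tibble::tibble(
      tension_peak = if (has("tension")) max(gsel$tension) else NA_real_,
      shortening_pct = if (has("shortening")) max(gsel$shortening) else
        NA_real_,
      OCR_amp = if (has("OCR")) diff(range(gsel$OCR)) else NA_real_,
      PSP_min = if (has("PSP")) min(gsel$PSP) else NA_real_,
      PSP_mean = if (has("PSP")) mean(gsel$PSP) else NA_real_,
      EAD_count = nrow(cdx_detect_ead(seg, beats = idx)),
      aftercontraction_count = if (has("tension"))
        nrow(cdx_detect_aftercontractions(seg, beats = idx)) else NA_integer_))
  out
}
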