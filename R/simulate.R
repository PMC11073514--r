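# Integration driver.
#
# Stiff variable-step integration (deSolve lsoda, an implicit BDF/Adams
# switching method of ode15s-like accuracy) of the compiled right-hand side,
# with the protocol schedule evaluated inside the compiled code.  Output is a
# tidy tibble: time + 33 states + the per-step currents, fluxes and
# couplings.

#' Run a whole-cell simulation
#'
#' @param protocol a `cardiox_protocol` object or a protocol name passed to
#'   [cdx_protocol()] (`"control"`, `"sev1"`, `"sev2"`, `"ir"`).
#' @param drug_dose levosimendan dose in uM (only used when `protocol` is a
#'   name).
#' @param duration run length in seconds; defaults to the protocol's
#'   standard duration (800 s control, 850 s ischemia, 1100 s IR).
#' @param y0 initial state; defaults to the packaged control steady state
#'   (IR runs start from it, as the protocol timeline prescribes).
#' @param dt_fine,dt_coarse output sampling (s) inside / outside the windows
#'   of interest.
#' @param fine_windows list of `c(start, end)` windows sampled at `dt_fine`;
#'   default: the final 60 s for plateau protocols, the ischemic +
#'   reperfusion phases for IR.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param maxsteps solver step budget between output points.
#' @param params model parameters (only used when `protocol` is a name).
#' @param ... passed to [cdx_protocol()] when `protocol` is a name
#'   (e.g. `apply_set = TRUE`, `iks_rescue`).
#' @return A `cardiox_sim` object: list with `trace` (tibble), `protocol`,
#'   `params`, `solver` settings and `wall_time`.
#' @export
#' @examples
#' \donttest{
#' sim <- cdx_simulate("control", duration = 60)
#' dplyr::glimpse(sim$trace[1:6])
#' }
cdx_simulate <- function(protocol = "control", drug_dose = 0,
                         duration = NULL, y0 = NULL,
                         dt_fine = 0.001, dt_coarse = 0.01,
                         fine_windows = NULL, rtol = 1e-6, atol = 1e-8,
                         maxsteps = 500000, params = cdx_parameters(), ...) {
  if (is.character(protocol))
    protocol <- cdx_protocol(protocol, params = params,
                             drug_dose = drug_dose, ...)
  stopifnot(inherits(protocol, "cardiox_protocol"))
  p <- protocol$params
  if (is.null(duration)) duration <- protocol$duration
  if (duration <= 0) rlang::abort("duration must be positive")
  if (rtol <= 0 || atol <= 0) rlang::abort("tolerances must be positive")
  if (is.null(y0)) y0 <- cdx_steady_state("control")
  y0 <- validate_state(y0)

  if (is.null(fine_windows)) {
    fine_windows <- if (protocol$name == "ir" && duration > 400)
      list(c(350, duration)) else list(c(max(0, duration - 60), duration))
  }
  times <- sim_times(duration, dt_fine, dt_coarse, fine_windows)

  po <- unname(p[cdx_cpp_param_names()])
  if (anyNA(po)) rlang::abort("parameter vector incomplete")
  env <- protocol$env[, cdx_cpp_mod_names(), drop = FALSE]
  nwin <- length(protocol$breaks) / 2
  cdx_set_parms_cpp(c(nrow(env), nwin, po, as.vector(t(env)),
                      protocol$breaks))
  t0 <- Sys.time()
  out <- deSolve::ode(unname(y0), times, func = "cdx_derivs", parms = NULL,
                      dllname = "cardiox", nout = length(cdx_current_names()),
                      outnames = cdx_current_names(), method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = maxsteps)
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (attr(out, "istate")[1] < 0)
    rlang::abort(sprintf(
      "solver failure at t = %.3f s (see diagnostics(); last state snapshot in $trace)",
      out[nrow(out), 1]))
  colnames(out) <- c("time", cdx_state_names(), cdx_current_names())
  trace <- tibble::as_tibble(as.data.frame(out))
  structure(list(trace = trace, protocol = protocol, params = p,
                 solver = list(method = "lsoda", rtol = rtol, atol = atol,
                               dt_fine = dt_fine, dt_coarse = dt_coarse),
                 y0 = y0, wall_time = wall),
            class = "cardiox_sim")
}

sim_times <- function(duration, dt_fine, dt_coarse, fine_windows) {
  tt <- seq(0, duration, by = dt_coarse)
  for (w in fine_windows) {
    a <- max(0, w[1]); b <- min(duration, w[2])
    if (b > a) tt <- c(tt, seq(a, b, by = dt_fine))
  }
  sort(unique(round(tt, 9)))
}

#' @export
print.cardiox_sim <- function(x, ...) {
  cat("<cardiox_sim>", x$protocol$name,
      sprintf("(%.0f s, %d samples, %.1f s wall)\n",
              max(x$trace$time), nrow(x$trace), x$wall_time))
  invisible(x)
}

#' @rdname cdx_simulate
#' @param x a `cardiox_sim` object.
#' @export
tidy.cardiox_sim <- function(x, ...) {
  x$trace
}

#' @rdname cdx_simulate
#' @export
glance.cardiox_sim <- function(x, ...) {
  b <- cdx_biomarkers(x)
  dplyr::bind_cols(
    tibble::tibble(protocol = x$protocol$name,
                   drug_dose = if (is.null(x$protocol$drug)) 0 else
                     x$protocol$drug$dose,
                   duration = max(x$trace$time),
                   wall_time = x$wall_time),
    b)
}
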