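# Shared long-running simulations, computed once per test session.

sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}

control_sim <- function() cached_sim("control", cdx_simulate("control"))

sev_sim <- function(level, dose = 0) {
  key <- paste0(level, "_", dose)
  cached_sim(key, cdx_simulate(level, drug_dose = dose, duration = 1050,
                               fine_windows = list(c(950, 1050))))
}

ir_sim <- function(dose = 0, iks_rescue = 1) {
  key <- paste0("ir_", dose, "_", iks_rescue)
  cached_sim(key, cdx_simulate("ir", drug_dose = dose,
                               iks_rescue = iks_rescue, dt_fine = 0.002))
}

steady_window <- c(950, 1050)

per_beat_means <- function(sim, window) {
  seg <- cdx_segment_beats(sim$trace, window = window)
  idx <- seq.int(max(1L, nrow(seg$beats) - 9L), nrow(seg$beats))
  slice <- function(i) {
    b <- seg$beats[i, ]
    seg$grid[seg$grid$time >= b$t_up & seg$grid$time < b$t_end, ]
  }
  list(
    iup = mean(vapply(idx, function(i) {
      g <- slice(i); sum((g$I_up[-1] + g$I_up[-nrow(g)]) / 2 * diff(g$time))
    }, 0)),
    casr = mean(vapply(idx, function(i) mean(slice(i)$Ca_SR), 0)),
    tension = mean(vapply(idx, function(i) max(slice(i)$tension), 0)))
}

# brute-force two-state Markov oracle: stationary distribution and net flux
two_state_oracle <- function(ap1, ap2, am1, am2) {
  # states: A (cytosolic lump), B (phosphorylated lump)
  # A -> B at ap1 + am2; B -> A at ap2 + am1
  Q <- matrix(c(-(ap1 + am2), ap1 + am2,
                ap2 + am1, -(ap2 + am1)), 2, 2, byrow = TRUE)
  # stationary: pi Q = 0, sum pi = 1 -> solve linear system
  A <- rbind(t(Q), c(1, 1))
  pi <- qr.solve(A, c(0, 0, 1))
  flux <- pi[1] * ap1 - pi[2] * am1 # net forward flux through edge 1
  list(pi = pi, flux = flux)
}
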