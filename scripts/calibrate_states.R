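#!/usr/bin/env Rscript

# Regenerates the packaged control steady state and the SERCA flux scale S.
#
# Recipe: (1) integrate the control model for 2000 s of spontaneous beating
# from the generic initial state; (2) iterate the flux-scale fixed point
# S <- max I_up(legacy saturating formulation, over the last beats) /
#      max v_cle(two-state pump, same beats)
# until converged; (3) freeze the final phase point into
# R/steady-states.R and serca_S into R/params.R (manual copy).

suppressPackageStartupMessages(library(cardiox))

y0 <- cdx_initial_state()
p <- cdx_parameters()
S <- p[["serca_S"]]
for (it in 1:6) {
  prm <- cdx_parameters(serca_S = S)
  sim <- cdx_simulate(cdx_protocol("control", params = prm),
                      duration = if (it == 1) 2000 else 400, y0 = y0)
  tr <- sim$trace
  o <- tr[tr$time > max(tr$time) - 60, ]
  legacy <- prm[["VmaxUp"]] / (1 + (prm[["Kup"]] / o$Ca_i)^2)
  S_new <- max(legacy) / max(o$v_cle)
  message(sprintf("iteration %d: S = %.6f -> %.6f", it, S, S_new))
  y0 <- setNames(as.numeric(tr[nrow(tr), 2:34]), cdx_state_names())
  if (abs(S_new - S) / S < 1e-4) { S <- S_new; break }
  S <- S_new
}
message("converged serca_S = ", format(S, digits = 6))
cat(paste(sprintf("%s = %.10g", names(y0), unname(y0)), collapse = ",\n"),
    "\n")
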