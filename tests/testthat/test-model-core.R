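# Whole-cell right-hand side.

random_state <- function(seed) {
  set.seed(seed)
  y <- cdx_initial_state()
  y[["V"]] <- runif(1, -0.09, 0.03)
  y[["Ca_i"]] <- runif(1, 1e-5, 1e-3)
  y[["Ca_SR"]] <- runif(1, 0.05, 0.5)
  y[["Na_i"]] <- runif(1, 6, 16)
  gates <- setdiff(cdx_state_names(),
                   c("V", "Ca_i", "Ca_SR", "Na_i", "x_A", "x_B", "SL", "O2_e"))
  y[gates] <- runif(length(gates))
  y[["SL"]] <- runif(1, 1.7, 1.95)
  y[["x_A"]] <- runif(1, -0.002, 0.002)
  y[["x_B"]] <- runif(1, 0, 0.01)
  y[["O2_e"]] <- runif(1, 0.02, 0.13)
  y
}

test_that("the state layout has exactly 33 entries with frozen names", {
  expect_length(cdx_state_names(), 33)
  expect_length(cdx_initial_state(), 33)
  expect_length(cdx_steady_state("control"), 33)
  expect_identical(names(cdx_initial_state()), cdx_state_names())
})

test_that("the reference R right-hand side and the compiled transcription
           agree to floating-point accuracy at random states", {
  p <- cdx_parameters()
  po <- unname(p[cardiox:::cdx_cpp_param_names()])
  m <- cdx_modifiers(p)
  mo <- unname(m[cardiox:::cdx_cpp_mod_names()])
  for (seed in 1:25) {
    y <- random_state(seed)
    rr <- cardiox:::rhs_core_r(0, y, p, m)
    rc <- cardiox:::cdx_rhs_point_cpp(0, unname(y), po, mo)
    expect_equal(unname(rr$dy), rc$dy, tolerance = 1e-12)
    expect_equal(unname(rr$out), rc$out, tolerance = 1e-12)
  }
})

test_that("the derivative is a pure function and rejects non-finite states", {
  y <- cdx_steady_state("control")
  d1 <- cdx_derivatives(0, y)
  d2 <- cdx_derivatives(0, y)
  expect_identical(d1, d2)
  bad <- y; bad[["Ca_i"]] <- NaN
  expect_error(cdx_derivatives(0, bad), "Ca_i")
  expect_error(cdx_derivatives(0, y[1:10]), "33")
})

test_that("scaling a single maximal conductance scales that current exactly
           and the oxygen coupling scales the pumps exactly", {
  p <- cdx_parameters()
  y <- random_state(3)
  base <- cdx_compute_currents(y, p, cdx_modifiers(p))
  half_na <- cdx_compute_currents(y, p, cdx_modifiers(p, sc_gNa = 0.5))
  expect_equal(half_na$I_Na, base$I_Na * 0.5, tolerance = 1e-12)
  expect_equal(half_na$I_CaL, base$I_CaL, tolerance = 1e-12)
  half_pump <- cdx_compute_currents(y, p, cdx_modifiers(p, f_NaK = 0.5))
  expect_equal(half_pump$I_NaK, base$I_NaK * 0.5, tolerance = 1e-12)
  half_pca <- cdx_compute_currents(y, p, cdx_modifiers(p, f_pCa = 0.5))
  expect_equal(half_pca$I_pCa, base$I_pCa * 0.5, tolerance = 1e-12)
})

test_that("the control model beats spontaneously with gates bounded and
           near-zero net ion drift per beat", {
  sim <- control_sim()
  o <- sim$trace[sim$trace$time > 740, ]
  gates <- c("m", "h", "j", "mL", "hL", "d", "f1", "f2", "fCa", "Xr1",
             "Xr2", "Xs", "Xf", "q", "r", "RyR_a", "RyR_o", "RyR_c")
  for (g in gates)
    expect_true(all(o[[g]] >= -1e-6 & o[[g]] <= 1 + 1e-6), label = g)
  b <- cdx_biomarkers(sim)
  expect_gt(b$rate_Hz, 0.3)
  expect_lt(b$rate_Hz, 1.2)
  expect_lt(b$MDP_mV, -70)
  # steady-cycle ion balance: beat-to-beat drift below 1% of the excursion
  seg <- cdx_segment_beats(sim$trace, window = c(740, 800))
  n <- nrow(seg$beats)
  b1 <- seg$beats[n - 7, ]; b2 <- seg$beats[n - 1, ]
  at <- function(tt, cn) approx(seg$grid$time, seg$grid[[cn]], tt)$y
  for (cn in c("Na_i", "Ca_i")) {
    # averaged over six beats so beat-to-beat jitter cancels
    drift <- abs(at(b2$t_up, cn) - at(b1$t_up, cn)) / 6
    exc <- diff(range(seg$grid[[cn]]))
    expect_lt(drift, 0.01 * exc)
  }
})

test_that("the equilibrium-clamped state produces near-zero concentration
           derivatives", {
  # a contrived rest state: all fluxes shut (gates closed, Ca at floor),
  # concentrations then move only through residual background pathways
  p <- cdx_parameters()
  y <- cdx_steady_state("control")
  m <- cdx_modifiers(p, sc_gNa = 0, sc_gNaL = 0, sc_gCaL = 0, sc_gbNa = 0,
                     sc_gbCa = 0, sc_kNCX = 0, sc_PNaK = 0, sc_girel = 0,
                     sc_Iup = 0, sc_leak = 0, sc_gpCa = 0, sc_gf = 0)
  d <- cdx_derivatives(0, y, p, m)
  expect_equal(d[["Na_i"]], 0, tolerance = 1e-10)
  # Ca moves only via the troponin flux at this snapshot
  ce <- cdx_ce_derivatives(y[cardiox:::ce_state_names], y[["Ca_i"]],
                           params = p)
  bufc <- 1 / (1 + p[["Buf_C"]] * p[["Kbuf_C"]] /
               (y[["Ca_i"]] + p[["Kbuf_C"]])^2)
  expect_equal(d[["Ca_i"]], -bufc * ce$J_trpn, tolerance = 1e-10)
})
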