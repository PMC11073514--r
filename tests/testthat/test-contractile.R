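# Mean-field contractile element.

ce_steady <- function(Ca_i, kon_scale = 1, params = cdx_parameters(),
                      metabolites = list(MgATP = 6.8, MgADP = 0.015,
                                         Pi = 2, pH = 7.15)) {
  # relax the CE subsystem at fixed Ca by explicit Euler (small system,
  # independent oracle for steady behaviour)
  s <- cdx_initial_state()[cardiox:::ce_state_names]
  for (i in 1:6000) {
    d <- cdx_ce_derivatives(s, Ca_i, metabolites, kon_scale, params)
    s <- s + 0.005 * d$deriv
    s[1:6] <- pmin(pmax(s[1:6], 0), 1)
  }
  list(state = s,
       out = cdx_ce_derivatives(s, Ca_i, metabolites, kon_scale, params))
}

test_that("occupancy groups are conserved along a whole-cell trajectory", {
  sim <- control_sim()
  o <- sim$trace[sim$trace$time > 760, ]
  expect_true(all(abs(o$trpn_T + o$trpn_TCa - 1) < 1e-6))
  expect_true(all(abs(o$xb_N + o$xb_P + o$xb_A + o$xb_B - 1) < 1e-6))
  occ <- c(o$trpn_T, o$trpn_TCa, o$xb_N, o$xb_P, o$xb_A, o$xb_B)
  expect_true(all(occ > -1e-8 & occ < 1 + 1e-8))
})

test_that("without calcium the bound troponin and tension decay to zero", {
  st <- ce_steady(0)
  expect_lt(st$state[["trpn_TCa"]], 1e-6)
  expect_lt(st$out$tension, 1e-3)
})

test_that("steady bound troponin increases strictly with the K_on scale and
           matches the closed form at fixed calcium", {
  ca <- 2e-4
  tca <- vapply(c(1, 1.25, 1.5, 2), function(k) ce_steady(ca, k)$state[["trpn_TCa"]], 0)
  expect_true(all(diff(tca) > 0))
  # closed form for the isolated troponin subsystem (no crossbridge load at
  # the xb feedback's fixed point value)
  p0 <- cdx_parameters(ce_xbfb = 0)
  st <- ce_steady(ca, 1, p0)
  expect_equal(st$state[["trpn_TCa"]], cdx_trpn_steady(ca), tolerance = 1e-3)
})

twitch_peak <- function(kon_scale = 1, params = cdx_parameters(),
                        metabolites = list(MgATP = 6.8, MgADP = 0.015,
                                           Pi = 2, pH = 7.15)) {
  # drive the CE with a prescribed periodic Ca transient (independent of the
  # whole-cell model) and report the steady twitch peak tension
  s <- cdx_initial_state()[cardiox:::ce_state_names]
  dt <- 0.002; peak <- 0
  for (i in seq_len(4000)) {
    tt <- i * dt; ph <- tt %% 1
    ca <- 2e-5 + 3e-4 * ph / 0.05 * exp(1 - ph / 0.05)
    d <- cdx_ce_derivatives(s, ca, metabolites, kon_scale, params)
    s <- s + dt * d$deriv
    s[1:6] <- pmin(pmax(s[1:6], 0), 1)
    if (tt > 7) peak <- max(peak, d$tension)
  }
  peak
}

test_that("steady twitch tension is non-decreasing in the K_on scale and
           depressed by ischemic metabolites", {
  tn <- vapply(c(1, 1.2, 1.5), function(k) twitch_peak(k), 0)
  expect_true(all(diff(tn) >= -1e-9))
  ctrl <- twitch_peak()
  isch <- twitch_peak(metabolites = list(MgATP = 4.6, MgADP = 0.099,
                                         Pi = 11, pH = 6.7))
  expect_lt(isch, ctrl)
})

test_that("the ATPase rate is in mM/s, nonnegative, and scales with the
           crossbridge site density", {
  st <- ce_steady(3e-4)
  expect_gte(st$out$ATPase, 0)
  p2 <- cdx_parameters(ce_rho_atp = 2 * cdx_parameters()[["ce_rho_atp"]])
  st2 <- ce_steady(3e-4, params = p2)
  expect_equal(st2$out$ATPase, 2 * st$out$ATPase, tolerance = 0.02)
})

test_that("invalid occupancies and non-positive kon scales are rejected", {
  s <- cdx_initial_state()[cardiox:::ce_state_names]
  s[["xb_N"]] <- 1.5
  expect_error(cdx_ce_derivatives(s, 1e-4), "integration fault")
  expect_error(cdx_ce_derivatives(cdx_initial_state()[cardiox:::ce_state_names],
                                  1e-4, kon_scale = 0), "positive")
})
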