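# Oxygen dynamics: gamma conversion, Fick rate, rho coupling, O2 balance.

test_that("the charge-utilization factor reproduces its printed value and
           scales inversely with cell volume", {
  g <- cdx_gamma_factor()
  expect_equal(g, 0.1163, tolerance = 2e-3)
  expect_equal(g, 98.7109e-12 / (96485.3415 * 8800e-18), tolerance = 1e-12)
  expect_equal(cdx_gamma_factor(V_c = 2 * 8800e-18), g / 2, tolerance = 1e-12)
})

test_that("the diffusive exchange rate has the packaged 5 1/s default, a bare
           Fick ratio of 2.5 1/s, and inverse-square distance scaling", {
  expect_equal(cdx_diffusion_rate(), 5)
  expect_equal(cdx_diffusion_rate(geometry = 1), 2.5)
  expect_equal(cdx_diffusion_rate(dx = 20e-6), 5 / 4)
  expect_error(cdx_diffusion_rate(D = -1), "positive")
})

test_that("rho is 1 at baseline oxygen, hits the severity anchors, and is a
           monotone bounded sigmoid", {
  p <- cdx_parameters()
  expect_equal(cdx_rho(p[["o2_source"]]), 1, tolerance = 1e-12)
  expect_equal(cdx_rho(cdx_o2s_for_rho(0.80)), 0.80, tolerance = 0.01)
  expect_equal(cdx_rho(cdx_o2s_for_rho(0.69)), 0.69, tolerance = 0.01)
  o2 <- seq(0, 1, by = 0.005)
  r <- cdx_rho(o2)
  expect_true(all(diff(r) > 0))
  base <- (p[["rho_a"]] + p[["rho_b"]] * p[["rho_K"]]) / (1 + p[["rho_K"]])
  expect_equal(cdx_rho(0), p[["rho_b"]] / base, tolerance = 1e-12)
  expect_equal(cdx_rho(1e6), p[["rho_a"]] / base, tolerance = 1e-3)
  # severity O2_s values are ordered control > SEV1 > SEV2
  o2s <- vapply(c("control", "SEV1", "SEV2"),
                function(l) cdx_severity_config(l)$O2_s, 0)
  expect_true(all(diff(o2s) < 0))
})

test_that("the oxygen balance has its fixed point at the source level with no
           consumption and responds to an ATPase step with a deeper draw", {
  expect_equal(cdx_o2_derivative(0.133, 0.133, 0, 0, 0), 0)
  d1 <- cdx_o2_derivative(0.11, 0.133, 0.3, 0.02, 0.05)
  d2 <- cdx_o2_derivative(0.11, 0.133, 0.3, 0.02, 0.25)
  expect_lt(d2, d1) # larger contractile ATP use -> more negative dO2/dt
})

test_that("a steady control beat splits ATP consumption about 79/21 between
           contraction and maintenance and keeps O2 inside [0, O2_s]", {
  sim <- control_sim()
  o <- sim$trace[sim$trace$time > 740, ]
  g <- cdx_gamma_factor()
  p <- cdx_parameters()
  maint <- p[["o2_beta"]] * g * (o$I_NaK + o$I_pCa)
  share <- mean(maint) / (mean(maint) + mean(o$ATPase))
  expect_equal(share, 0.21, tolerance = 0.25) # recovered from the trace
  expect_true(all(o$O2_e >= 0 & o$O2_e <= p[["o2_source"]]))
})
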