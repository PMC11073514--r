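# ATP-sensitive K+ current.

test_that("open fraction is monotone in the nucleotides and ordered across
           the ischemic severities", {
  atp <- seq(0.5, 10, by = 0.5)
  for (adp in c(0.01, 0.05, 0.1)) {
    f <- cdx_f_katp(atp, adp)
    expect_true(all(diff(f) < 0)) # strictly decreasing in MgATP
    expect_true(all(f >= 0 & f <= 1))
  }
  adp <- seq(0.005, 0.2, by = 0.005)
  for (a in c(3, 5, 8)) {
    f <- cdx_f_katp(a, adp)
    expect_true(all(diff(f) > 0)) # increasing in MgADP
  }
  cfg <- lapply(c("control", "SEV1", "SEV2"), cdx_severity_config)
  f3 <- vapply(cfg, function(x) x$f_KATP, 0)
  expect_true(f3[1] < f3[2] && f3[2] < f3[3])
  # ATP-free limit: no inhibitor, channels fully available
  expect_equal(cdx_f_katp(0, 0.015), 1)
})

test_that("the R transcription of the open fraction matches the independent
           compiled transcription", {
  p <- cdx_parameters()
  po <- unname(p[cardiox:::cdx_cpp_param_names()])
  y <- cdx_initial_state()
  set.seed(7)
  for (i in 1:20) {
    m <- cdx_modifiers(p, MgATP = runif(1, 0.5, 8), MgADP = runif(1, 0.005, 0.2))
    mo <- unname(m[cardiox:::cdx_cpp_mod_names()])
    out <- cardiox:::cdx_rhs_point_cpp(0, unname(y), po, mo)$out
    f_cpp <- out[match("f_KATP", cardiox:::cdx_current_names())]
    expect_equal(f_cpp, cdx_f_katp(m[["MgATP"]], m[["MgADP"]], p),
                 tolerance = 1e-12)
  }
})

test_that("the current is proportional to the open fraction times the drug
           scale and vanishes with closed channels", {
  p <- cdx_parameters()
  V <- -0.02; Ko <- 5.4
  expect_equal(cdx_i_katp(V, Ko, 0, 1, p), 0)
  base <- cdx_i_katp(V, Ko, 0.004, 1, p)
  expect_equal(cdx_i_katp(V, Ko, 0.008, 1, p), 2 * base, tolerance = 1e-12)
  expect_equal(cdx_i_katp(V, Ko, 0.004, 1.84, p), 1.84 * base,
               tolerance = 1e-12)
  # outward above E_K
  expect_gt(base, 0)
  # K_o dependence of the maximal conductance: (K_o/K_o,ref)^0.24 at fixed
  # driving force is monotone increasing
  f1 <- cdx_i_katp(0, 9, 0.01, 1, p) / (0 - p[["R_gas"]] * p[["Temp"]] /
    p[["Frdy"]] * log(9 / p[["K_i"]]))
  f2 <- cdx_i_katp(0, 5, 0.01, 1, p) / (0 - p[["R_gas"]] * p[["Temp"]] /
    p[["Frdy"]] * log(5 / p[["K_i"]]))
  expect_gt(f1, f2)
  expect_error(cdx_f_katp(-1, 0.01), "non-negative")
})
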