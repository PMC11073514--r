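# Severity configurations, transitions, IR schedule and the drug model.

test_that("severity configurations carry the prescribed environment and are
           monotone from control to severe ischemia", {
  c0 <- cdx_severity_config("control")
  s1 <- cdx_severity_config("SEV1")
  s2 <- cdx_severity_config("SEV2")
  expect_equal(s1$K_o, 6.25)
  expect_equal(s2$K_o, 9)
  expect_equal(s2$sc_gCaL, 0.75)
  expect_equal(s1$sc_gCaL, 0.875)
  expect_equal(c0$K_o, 5)
  expect_equal(c0$O2_s, 0.133)
  expect_true(all(c0$sc_gNa == 1, c0$sc_gCaL == 1))
  for (f in c("K_o", "MgADP", "Pi"))
    expect_true(c0[[f]] < s1[[f]] && s1[[f]] < s2[[f]], label = f)
  for (f in c("pH", "MgATP", "O2_s", "sc_gNa", "sc_gCaL", "rho"))
    expect_true(c0[[f]] > s1[[f]] && s1[[f]] > s2[[f]], label = f)
})

test_that("the ouabain-like transition clamps outside its window and is a
           strictly monotone continuous path inside", {
  tt <- seq(200, 400, by = 0.5)
  v <- cdx_transition_profile(tt, 250, 350, 5, 6.25)
  expect_equal(v[tt <= 250], rep(5, sum(tt <= 250)))
  expect_equal(v[tt >= 350], rep(6.25, sum(tt >= 350)))
  inside <- v[tt > 250 & tt < 350]
  expect_true(all(diff(inside) > 0))
  mid <- cdx_transition_profile(300, 250, 350, 5, 6.25)
  expect_gt(mid, 5); expect_lt(mid, 6.25)
  # concave fast-onset shape: more than half the change by mid-window
  expect_gt((mid - 5) / 1.25, 0.5)
  expect_error(cdx_transition_profile(1, 10, 5, 0, 1), "before")
})

test_that("scheduled environments are continuous in time and match the
           R transition profile", {
  for (nm in c("sev2", "ir")) {
    pr <- cdx_protocol(nm, drug_dose = if (nm == "ir") 2 else 0)
    tt <- seq(0, pr$duration, by = 0.25)
    env <- cdx_protocol_env(pr, tt)
    for (cn in setdiff(names(env), "time")) {
      x <- env[[cn]]
      scale <- max(abs(x)) + 1e-9
      expect_lt(max(abs(diff(x))) / scale, 0.05, label = paste(nm, cn))
    }
  }
  # C schedule evaluation equals the R-side transition profile
  pr <- cdx_protocol("sev1")
  tt <- seq(240, 360, by = 1)
  env <- cdx_protocol_env(pr, tt)
  expect_equal(env$K_o,
               cdx_transition_profile(tt, 250, 350, 5, 6.25),
               tolerance = 1e-12)
})

test_that("the IR schedule blocks the delayed rectifiers by 85% during the
           ischemic phase only and restores physoxia afterwards", {
  pr <- cdx_protocol("ir")
  set <- cdx_set_profile()
  mid <- cdx_protocol_env(pr, 500)
  expect_equal(mid$sc_gKr, 0.15 * set[["sc_gKr"]], tolerance = 1e-12)
  expect_equal(mid$K_o, 6.25, tolerance = 1e-12)
  early <- cdx_protocol_env(pr, 100)
  expect_equal(early$sc_gKr, set[["sc_gKr"]], tolerance = 1e-12)
  expect_equal(early$K_o, 5, tolerance = 1e-12)
  late <- cdx_protocol_env(pr, 1050)
  expect_equal(late$O2_s, 0.133, tolerance = 1e-12)
  expect_equal(late$sc_gKs, set[["sc_gKs"]], tolerance = 1e-12)
})

test_that("the Hill pore block has its textbook anchor points", {
  expect_equal(cdx_channel_block(0, 10, 1), 0)
  expect_equal(cdx_channel_block(10, 10, 1), 0.5)
  expect_equal(cdx_channel_block(100, 10, 1), 10 / 11)
  expect_error(cdx_channel_block(-1, 10), "non-negative")
})

test_that("the levosimendan bundle is the identity at dose zero and combines
           block, sensitization and channel opening at study doses", {
  m0 <- cdx_apply_levo(0)
  expect_equal(m0, cdx_modifiers())
  sp <- cdx_levo_spec(2)
  expect_gt(sp$kon_scale, 1)
  expect_gt(sp$fkatp_scale, 1)
  expect_true(all(sp$blocks$block >= 0 & sp$blocks$block < 1))
  # the 10 uM opener anchor: +84% K_ATP current
  expect_equal(cdx_levo_spec(10)$fkatp_scale, 1.84, tolerance = 1e-12)
  m <- cdx_apply_levo(2)
  expect_lt(m[["sc_gKr"]], 1)
  expect_equal(m[["kon_scale"]], sp$kon_scale)
  # log-dose interpolation between calibrated points is monotone
  doses <- c(0.3, 0.7, 1.5, 2, 5, 10)
  kon <- vapply(doses, function(d) cdx_levo_spec(d)$kon_scale, 0)
  expect_true(all(diff(kon) > 0))
})

test_that("the default modifier bundle is the identity environment", {
  m <- cdx_modifiers()
  sc <- m[grepl("^sc_|_mult$|_scale$|^f_", names(m))]
  expect_true(all(sc == 1))
  p <- cdx_parameters()
  expect_equal(m[["K_o"]], p[["K_o"]])
  expect_equal(m[["O2_s"]], p[["o2_source"]])
  expect_error(cdx_modifiers(nonsense = 2), "unknown modifier")
})

test_that("modifier and parameter name tables agree between R and the
           compiled core", {
  expect_identical(names(cdx_modifiers()),
                   as.character(cardiox:::cdx_cpp_mod_names()))
  expect_setequal(names(cdx_parameters()),
                  as.character(cardiox:::cdx_cpp_param_names()))
})
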