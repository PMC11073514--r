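# Integration driver, determinism, outputs.

test_that("identical configurations give identical traces and biomarkers", {
  a <- cdx_simulate("control", duration = 30)
  b <- cdx_simulate("control", duration = 30)
  expect_identical(a$trace, b$trace)
  expect_identical(cdx_biomarkers(a, window = c(0, 30)),
                   cdx_biomarkers(b, window = c(0, 30)))
})

test_that("tightening the solver tolerances changes biomarkers by well under
           half a percent", {
  y0 <- cdx_steady_state("control")
  a <- cdx_biomarkers(cdx_simulate("control", duration = 40, y0 = y0,
                                   rtol = 1e-6, atol = 1e-8),
                      window = c(5, 40))
  b <- cdx_biomarkers(cdx_simulate("control", duration = 40, y0 = y0,
                                   rtol = 2.5e-7, atol = 2.5e-9),
                      window = c(5, 40))
  for (cn in c("rate_Hz", "APD90_ms", "tDecay9010_ms", "MDP_mV"))
    expect_equal(a[[cn]], b[[cn]], tolerance = 5e-3, label = cn)
})

test_that("outputs round-trip through CSV/JSON and the manifest hash tracks
           the configuration", {
  sim <- cdx_simulate("control", duration = 5)
  dir <- withr::local_tempdir()
  paths <- cdx_write_outputs(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["trace"]])
  expect_equal(back$V, sim$trace$V, tolerance = 1e-12)
  expect_equal(names(back), names(sim$trace))
  m1 <- cdx_run_manifest(sim)
  m2 <- cdx_run_manifest(cdx_simulate("control", duration = 5))
  expect_identical(m1$config_hash, m2$config_hash)
  sim3 <- cdx_simulate("control", duration = 5, rtol = 1e-7)
  expect_false(identical(m1$config_hash, cdx_run_manifest(sim3)$config_hash))
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(cdx_simulate("control", duration = -1), "positive")
  expect_error(cdx_simulate("control", duration = 5, rtol = 0), "positive")
  expect_error(cdx_simulate("nope"), "arg")
})

test_that("tidy and glance methods expose the trace and a one-row summary", {
  sim <- cdx_simulate("control", duration = 40)
  expect_identical(tidy(sim), sim$trace)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$protocol, "control")
  expect_true("rate_Hz" %in% names(g))
})

test_that("autoplot and the protocol/pCa plots return ggplot objects", {
  sim <- cdx_simulate("control", duration = 10)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(cdx_plot_protocol(cdx_protocol("ir")), "ggplot")
  expect_s3_class(cdx_plot_pca_curve(cdx_pca_curve(pH = c(7.2, 6.5))),
                  "ggplot")
})
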