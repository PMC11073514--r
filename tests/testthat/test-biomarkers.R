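# Biomarker extraction against closed-form fixtures and basic invariants.

test_that("a periodic triangular AP train is segmented at the true rate and
           its AP metrics match the closed forms within 0.5%", {
  fx <- cdx_make_fixture("ap_train", period = 1.25, n_beats = 14)
  tr <- attr(fx, "truth")
  seg <- cdx_segment_beats(fx)
  expect_equal(nrow(seg$beats), tr$n_beats - 1) # last upstroke closes a beat
  ap <- cdx_ap_metrics(seg)
  expect_equal(ap$rate_Hz, tr$rate_Hz, tolerance = 0.005)
  expect_equal(ap$APD90_ms, tr$APD90_ms, tolerance = 0.005)
  # shorter APDs carry the same ~1 ms grid quantization: bound absolutely
  expect_lt(abs(ap$APD50_ms - tr$APD50_ms), 2)
  expect_lt(abs(ap$APD30_ms - tr$APD30_ms), 2)
  expect_equal(ap$MDP_mV, tr$MDP_mV, tolerance = 0.005)
  expect_equal(ap$dVdt_max, tr$dVdt_max, tolerance = 0.005)
})

test_that("a single-exponential calcium transient yields tDecay90,10 equal to
           log(9)/k within 0.5%", {
  for (k in c(5, 10, 20)) {
    fx <- cdx_make_fixture("cat_exp", k = k, period = 3, n_beats = 6)
    seg <- cdx_segment_beats(fx)
    cm <- cdx_cat_metrics(seg)
    expect_equal(cm$tDecay9010_ms, log(9) / k * 1000, tolerance = 0.005)
    expect_equal(cm$CaT_amp_mM, attr(fx, "truth")$CaT_amp_mM,
                 tolerance = 0.01)
  }
})

test_that("a flat trace reports zero beats without error", {
  flat <- tibble::tibble(time = seq(0, 10, by = 1e-3), V = -0.08)
  seg <- cdx_segment_beats(flat)
  expect_equal(nrow(seg$beats), 0)
  ap <- cdx_ap_metrics(seg)
  expect_true(is.na(ap$rate_Hz))
  expect_equal(ap$n_beats, 0L)
})

test_that("injected EAD humps are detected once per beat and clean beats
           yield none", {
  clean <- cdx_segment_beats(cdx_make_fixture("ap_ead", bump = FALSE))
  expect_equal(nrow(cdx_detect_ead(clean)), 0)
  bumped <- cdx_segment_beats(cdx_make_fixture("ap_ead", bump = TRUE))
  ev <- cdx_detect_ead(bumped)
  expect_equal(nrow(ev), nrow(bumped$beats))
  expect_equal(length(unique(ev$beat)), nrow(bumped$beats))
})

test_that("injected diastolic tension bumps are detected as
           aftercontractions and clean twitches yield none", {
  clean <- cdx_segment_beats(cdx_make_fixture("twitch", bump = FALSE))
  expect_equal(nrow(cdx_detect_aftercontractions(clean)), 0)
  bumped <- cdx_segment_beats(cdx_make_fixture("twitch", bump = TRUE))
  ev <- cdx_detect_aftercontractions(bumped)
  expect_equal(nrow(ev), nrow(bumped$beats))
})

test_that("noisy fixtures regenerate byte-identically under a fixed seed", {
  a <- cdx_make_fixture("twitch", noise_sd = 0.01, seed = 11)
  b <- cdx_make_fixture("twitch", noise_sd = 0.01, seed = 11)
  expect_identical(a, b)
  c <- cdx_make_fixture("twitch", noise_sd = 0.01, seed = 12)
  expect_false(identical(a$tension, c$tension))
})

test_that("reverse-mode NCX integration is zero for purely forward traces
           and positive otherwise", {
  fx <- cdx_make_fixture("ap_train")
  fx$I_NCX <- -abs(sin(2 * pi * fx$time)) # forward only
  seg <- cdx_segment_beats(fx)
  expect_equal(cdx_ncx_reverse_integral(seg)$ncx_reverse_area, 0)
  fx$I_NCX <- sin(2 * pi * fx$time) # half reverse
  seg2 <- cdx_segment_beats(fx)
  expect_gt(cdx_ncx_reverse_integral(seg2)$ncx_reverse_area, 0)
})

test_that("APD thresholds are ordered and control metrics are stable across
           the last beats", {
  sim <- control_sim()
  seg <- cdx_segment_beats(sim$trace, window = c(740, 800))
  ap <- cdx_ap_metrics(seg)
  expect_lte(ap$APD30_ms, ap$APD50_ms)
  expect_lte(ap$APD50_ms, ap$APD90_ms)
  per <- attr(ap, "per_beat")
  expect_lt(sd(per$APD90_ms) / mean(per$APD90_ms), 0.01)
  # the ~3 ms upstroke is sampled at 1 ms, so its peak estimate carries a
  # few percent of per-beat jitter
  expect_lt(sd(per$dVdt_max) / mean(per$dVdt_max), 0.10)
})
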