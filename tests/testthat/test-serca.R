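# Two-state thermodynamic SERCA pump.

test_that("cycle rate and phosphorylated-state occupancy match the
           brute-force two-state Markov oracle", {
  set.seed(42)
  for (i in 1:50) {
    r <- as.list(setNames(runif(4, 0.01, 50), c("ap1", "ap2", "am1", "am2")))
    orc <- two_state_oracle(r$ap1, r$ap2, r$am1, r$am2)
    expect_equal(cdx_serca_cycle_rate(r), orc$flux, tolerance = 1e-12)
    expect_equal(cdx_serca_psp(r), orc$pi[2], tolerance = 1e-12)
    expect_gte(cdx_serca_psp(r), 0)
    expect_lte(cdx_serca_psp(r), 1)
  }
})

test_that("flux vanishes exactly at detailed balance and follows the sign of
           ap1*ap2 - am1*am2", {
  r <- list(ap1 = 3, ap2 = 8, am1 = 4, am2 = 6) # 24 = 24
  expect_equal(cdx_serca_cycle_rate(r), 0)
  expect_gt(cdx_serca_cycle_rate(list(ap1 = 3.1, ap2 = 8, am1 = 4, am2 = 6)), 0)
  expect_lt(cdx_serca_cycle_rate(list(ap1 = 2.9, ap2 = 8, am1 = 4, am2 = 6)), 0)
  # swapping forward and backward rate pairs negates the flux
  fwd <- list(ap1 = 5, ap2 = 2, am1 = 0.3, am2 = 0.7)
  bwd <- list(ap1 = 0.3, ap2 = 0.7, am1 = 5, am2 = 2)
  expect_equal(cdx_serca_cycle_rate(fwd), -cdx_serca_cycle_rate(bwd),
               tolerance = 1e-14)
  # per-edge symmetric rates give PSP = 1/2
  expect_equal(cdx_serca_psp(list(ap1 = 2, ap2 = 7, am1 = 2, am2 = 7)), 0.5)
})

test_that("the Haldane wiring makes the flux vanish when the transport
           reaction free energy is zero", {
  p <- cdx_parameters()
  RT <- p[["R_gas"]] * p[["Temp"]]
  keq_mM <- exp(-p[["serca_dGATP0"]] / RT) * 1e3
  # choose concentrations satisfying
  # CaSR^2 * ADP * Pi * Hi^n / (Cai^2 * ATP * Hsr^n) = keq (equal pH)
  Cai <- 1e-4; ATP <- 5; ADP <- 0.02; Pi <- 1
  CaSR2 <- keq_mM * Cai^2 * ATP / (ADP * Pi)
  inp <- cdx_serca_input(Ca_i = Cai, Ca_SR = sqrt(CaSR2), pH = 7.0,
                         MgATP = ATP, MgADP = ADP, Pi = Pi)
  r <- cdx_serca_rates(inp, p)
  expect_equal(cdx_serca_cycle_rate(r), 0, tolerance = 1e-10)
  # slightly richer ATP -> forward; slightly poorer -> backward
  inp2 <- cdx_serca_input(Cai, sqrt(CaSR2), 7.0, ATP * 1.01, ADP, Pi)
  expect_gt(cdx_serca_cycle_rate(cdx_serca_rates(inp2, p)), 0)
  inp3 <- cdx_serca_input(Cai, sqrt(CaSR2), 7.0, ATP * 0.99, ADP, Pi)
  expect_lt(cdx_serca_cycle_rate(cdx_serca_rates(inp3, p)), 0)
})

test_that("no cytosolic calcium means no forward cycling", {
  inp <- cdx_serca_input(Ca_i = 0, Ca_SR = 0.3)
  r <- cdx_serca_rates(inp)
  expect_equal(r$ap1, 0)
  expect_lte(cdx_serca_cycle_rate(r), 0)
})

test_that("physiological control input cycles forward and acidification
           slows the pump at fixed calcium", {
  inp <- cdx_serca_input(Ca_i = 2e-4, Ca_SR = 0.3, pH = 7.15)
  expect_gt(cdx_serca_cycle_rate(cdx_serca_rates(inp)), 0)
  pH_grid <- seq(7.4, 6.0, by = -0.1)
  for (ca in c(3e-5, 2e-4, 1e-3, 1e-2)) {
    rates <- cdx_serca_cycle_rate(cdx_serca_rates(
      cdx_serca_input(Ca_i = ca, Ca_SR = 0.3, pH = pH_grid)))
    expect_true(all(diff(rates) <= 1e-12),
                label = sprintf("monotone non-increasing with acidity (Ca=%g)", ca))
  }
})

test_that("pump-rate versus pCa curves saturate in calcium and shift toward
           higher calcium as pH falls", {
  cv <- cdx_pca_curve(pH = c(7.2, 6.9, 6.5), pCa = seq(8, 4, by = -0.05))
  for (ph in unique(cv$pH)) {
    one <- cv[cv$pH == ph, ]
    expect_true(all(diff(one$rate) >= -1e-9)) # monotone in [Ca2+]
    # saturation: last decade gains little
    expect_lt(one$rate[nrow(one)] - one$rate[nrow(one) - 20],
              0.05 * one$rate[nrow(one)])
  }
  # half-activation pCa decreases with acidity
  half_pca <- vapply(unique(cv$pH), function(ph) {
    one <- cv[cv$pH == ph, ]
    one$pCa[which(one$rate >= max(one$rate) / 2)[1]]
  }, 0)
  expect_true(all(diff(half_pca) <= 0) || all(diff(rev(half_pca)) <= 0))
  expect_lt(half_pca[3], half_pca[1]) # pH 6.5 needs more Ca than pH 7.2
  # rising-phase rates are lower at acidic pH
  mid <- cv[abs(cv$pCa - 6.4) < 1e-9, ]
  expect_lt(mid$rate[mid$pH == 6.5], mid$rate[mid$pH == 7.2])
})

test_that("ischemic recalibration keeps multipliers within bounds, control is
           the identity, and the acidic-zone shift is preserved", {
  expect_equal(unname(cardiox:::serca_ischemic_multipliers("control")),
               rep(1, 5))
  for (lev in c("SEV1", "SEV2")) {
    m <- cardiox:::serca_ischemic_multipliers(lev)
    expect_true(all(m >= 0.1 & m <= 5))
    pr <- cdx_serca_ischemic(severity = lev)
    cv <- cdx_pca_curve(pr, pH = c(7.2, 6.5), pCa = seq(8, 4, by = -0.05))
    half_pca <- vapply(c(7.2, 6.5), function(ph) {
      one <- cv[cv$pH == ph, ]
      one$pCa[which(one$rate >= max(one$rate) / 2)[1]]
    }, 0)
    expect_lt(half_pca[2], half_pca[1]) # still right-shifted when acidic
  }
})

test_that("the flux scale factor rescales the cycling rate linearly and
           rejects non-positive scales", {
  p <- cdx_parameters()
  expect_equal(cdx_serca_flux(0, p), 0)
  expect_equal(cdx_serca_flux(2, p), 2 * p[["serca_S"]])
  expect_error(cdx_serca_flux(1, cdx_parameters(serca_S = -1)), "positive")
})
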