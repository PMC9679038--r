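test_that("oxygen saturation curve has the right anchors and bounds", {
  expect_identical(o2_saturation(0, default_params), 0)
  expect_equal(o2_saturation(default_params$p50, default_params), 0.5,
               tolerance = 1e-9)
  hill <- mwc_params(mode = "hill", p50 = 26, n_hill = 2.7)
  expect_equal(o2_saturation(26, hill), 0.5)
  p_grid <- seq(0, 200, by = 2)
  y <- o2_saturation(p_grid, default_params)
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(diff(y) > 0))
  expect_error(o2_saturation(-1, default_params), "non-negative")
})

test_that("equal-affinity states collapse the curve to the hyperbola for any L", {
  p_grid <- seq(0.1, 100, length.out = 40)
  for (L in c(1, 1e3, 1e7)) {
    pars <- mwc_params(L = L, c = 1, KR = 5)
    a <- p_grid / 5
    expect_equal(o2_saturation(p_grid, pars), a / (1 + a), tolerance = 1e-12)
  }
})

test_that("quaternary-state fractions are complementary, monotone and correct", {
  pars <- mwc_params(L = 10, c = 0.1, KR = 1)
  expect_equal(r_state_fraction(10, pars), 11^4 / (11^4 + 10 * 2^4),
               tolerance = 1e-9)
  expect_equal(r_state_fraction(0, pars), 1 / (1 + 10), tolerance = 1e-12)
  # high-pressure limit: fR -> 1/(1 + L c^4), close to (but not exactly) 1
  expect_equal(r_state_fraction(1e8, pars), 1 / (1 + 10 * 0.1^4),
               tolerance = 1e-4)
  expect_gt(r_state_fraction(1e8, pars), 0.99)
  fr <- r_state_fraction(seq(0, 50, by = 0.5), pars)
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(r_state_fraction(10, mwc_params(mode = "hill")), "two-state")
})

test_that("saturation inversion is the exact inverse of the binding curve", {
  s_grid <- seq(0.05, 0.95, by = 0.1)
  p <- saturation_to_pO2(s_grid, default_params)
  expect_equal(o2_saturation(p, default_params), s_grid, tolerance = 1e-8)
  hill <- mwc_params(mode = "hill", p50 = 26)
  expect_equal(saturation_to_pO2(0.5, hill), 26, tolerance = 1e-6)
  expect_error(saturation_to_pO2(1, default_params), "strictly inside")
  expect_error(saturation_to_pO2(0, default_params), "strictly inside")
})

test_that("KR calibration places half-saturation at the requested P50", {
  pars <- calibrate_KR(mwc_params(), 30)
  expect_equal(o2_saturation(30, pars), 0.5, tolerance = 1e-6)
  # non-cooperative closed form: KR equals the target P50
  flat <- calibrate_KR(mwc_params(c = 1, KR = 3), 17)
  expect_equal(flat$KR, 17, tolerance = 1e-6)
  # hill mode: KR untouched, p50 set
  h <- calibrate_KR(mwc_params(mode = "hill"), 22)
  expect_equal(h$p50, 22)
})

test_that("stoichiometric release is monotone in saturation and bounded by capacity", {
  hb <- hb_default_mM
  full <- gsh_linkage(phi = 1)
  rel0 <- stoichiometric_release(0, hb, full, default_params)
  expect_equal(rel0, max_release_capacity(hb, 2) * default_params$L /
                 (1 + default_params$L), tolerance = 1e-9)
  expect_lt(abs(rel0 - 10.47), 0.01)
  expect_lt(stoichiometric_release(1, hb, full, default_params), 1e-12)
  rel <- stoichiometric_release(seq(0, 1, by = 0.05), hb, full, default_params)
  expect_true(all(diff(rel) <= 0))
  expect_error(stoichiometric_release(0.5, -1), "non-negative")
  expect_error(stoichiometric_release(1.2, hb), "fraction")
})

test_that("predicted free GSH is flat-then-rising and anchored at the baseline", {
  v <- predicted_free_gsh(c(0.2, 0.5, 0.9, 1), 1.23, hb_default_mM,
                          default_linkage, default_params)
  expect_true(all(diff(v) < 0))
  expect_equal(v[4], 1.23) # fully oxygenated: exactly the baseline
})

test_that("equilibrium free GSH solves the analytic quadratic and conserves mass", {
  # fR = 1, n_r = 4, kd_r = 2 uM, hb = 1 uM, g_total = 4 uM -> g = 2 uM
  g <- equilibrium_free_gsh(4e-3, 1e-3, SO2 = 1, gsh_linkage(), default_params)
  expect_equal(g, 2e-3, tolerance = 1e-6)
  expect_identical(equilibrium_free_gsh(2, 0, 0.5), 2)
  # no-binding limit: at Kd = 1e6 uM the bound pool is ~ n*hb*g/kd, ~2%
  weak <- gsh_linkage(kd_r = 1e6, kd_t = 1e6)
  expect_equal(equilibrium_free_gsh(2, 5, 0.5, weak, default_params), 2,
               tolerance = 0.03)
  # mass conservation across random conditions
  set.seed(21)
  for (i in 1:15) {
    lk <- gsh_linkage(kd_r = runif(1, 1, 50), kd_t = runif(1, 1, 50))
    g_tot <- runif(1, 0.01, 5)
    hb <- runif(1, 0.1, 6)
    so2 <- runif(1, 0.05, 0.95)
    g <- equilibrium_free_gsh(g_tot, hb, so2, lk, default_params)
    fT <- 1 - r_state_fraction(saturation_to_pO2(so2, default_params),
                               default_params)
    bound <- hb * ((1 - fT) * lk$n_r * g / (g + lk$kd_r / 1000) +
                     fT * lk$n_t * g / (g + lk$kd_t / 1000))
    expect_equal(g + bound, g_tot, tolerance = 1e-9)
  }
})

test_that("GSH left-shifts and BPG right-shifts the oxygen equilibrium curve", {
  base <- p50_with_gsh(0, default_linkage, default_params)
  expect_equal(base, default_params$p50, tolerance = 1e-6)
  p50_g <- vapply(c(0.05, 0.2, 1, 5), p50_with_gsh, numeric(1),
                  linkage = default_linkage, params = default_params)
  expect_true(all(diff(c(base, p50_g)) < 0)) # strictly decreasing in GSH
  bpg <- bpg_linkage()
  p50_b <- vapply(c(0.5, 2, 5), function(b) {
    p50_with_gsh(0, default_linkage, default_params, bpg = bpg, bpg_mM = b)
  }, numeric(1))
  expect_true(all(diff(c(base, p50_b)) > 0)) # strictly increasing in BPG
})

test_that("release is concentrated at low saturation with the calibrated defaults", {
  r_low <- stoichiometric_release(0.2, hb_default_mM, default_linkage,
                                  default_params)
  r_high <- stoichiometric_release(0.9, hb_default_mM, default_linkage,
                                   default_params)
  expect_lt(r_high, 0.2 * r_low)
})

test_that("threshold estimator recovers a noiseless threshold and rejects flat data", {
  so2 <- seq(0.98, 0.05, by = -0.03)
  g <- threshold_curve(so2, s_star = 0.5)
  fit <- estimate_threshold(so2, g)
  expect_true(fit$threshold_found)
  expect_equal(fit$threshold, 0.5, tolerance = 0.011)
  flat <- estimate_threshold(so2, rep(2.5, length(so2)))
  expect_false(flat$threshold_found)
  expect_true(is.na(flat$threshold))
  noisy_flat <- estimate_threshold(so2, 2.5 + sin(seq_along(so2)) * 0) # exact flat again
  expect_false(noisy_flat$threshold_found)
  expect_error(estimate_threshold(so2[1:5], g[1:5]), "at least 10")
})

test_that("occupancy fit inverts the release model", {
  so2 <- seq(0.05, 0.98, length.out = 25)
  truth <- predicted_free_gsh(so2, 1.23, hb_default_mM,
                              gsh_linkage(phi = 0.17), default_params)
  fit <- fit_phi(so2, truth, hb_default_mM, default_linkage, default_params)
  expect_equal(fit$phi, 0.17, tolerance = 1e-6)
  expect_equal(fit$baseline_mM, 1.23, tolerance = 1e-6)
  # zero release: occupancy clipped at zero
  none <- fit_phi(so2, rep(1.23, 25), hb_default_mM, default_linkage,
                  default_params)
  expect_equal(none$phi, 0)
  expect_error(fit_phi(rep(0.5, 6), rep(1.3, 6), hb_default_mM),
               "identifiable")
})
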