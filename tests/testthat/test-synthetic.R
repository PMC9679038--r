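test_that("every generator is a pure function of parameters and seed", {
  expect_identical(generate_cohort(seed = 3), generate_cohort(seed = 3))
  expect_false(identical(generate_cohort(seed = 3), generate_cohort(seed = 4)))
  sc <- tonometry_scenario()
  expect_identical(generate_tonometry(sc, seed = 3), generate_tonometry(sc, seed = 3))
  th <- itc_thermo(4, 5e5, -20)
  expect_identical(generate_itc(thermo = th, noise_sd_uJ = 2, seed = 3),
                   generate_itc(thermo = th, noise_sd_uJ = 2, seed = 3))
  expect_identical(generate_standard_additions(1.8, 3, noise_sd = 0.1, seed = 3),
                   generate_standard_additions(1.8, 3, noise_sd = 0.1, seed = 3))
})

test_that("noise-free cohorts sit exactly at the configured condition means", {
  pars <- cohort_params(gsh_sd_sl = 0, gsh_sd_ha = 0, gssg_sd = 0,
                        so2_sd = 0, hb_sd = 0, subject_sd = 0)
  tab <- generate_cohort(cohort_design(n_subjects = 3), pars, seed = 1)
  expect_true(all(tab$gsh_umol_per_gHb[tab$condition == "HA"] == 4.6))
  expect_true(all(tab$gsh_umol_per_gHb[tab$condition == "SL"] == 3.4))
  expect_true(all(tab$so2_percent[tab$condition == "HA"] == 45))
})

test_that("large cohorts concentrate around the configured means", {
  tab <- generate_cohort(cohort_design(n_subjects = 500), cohort_params(),
                         seed = 5)
  expect_lt(abs(mean(tab$gsh_umol_per_gHb[tab$condition == "HA"]) - 4.6), 0.1)
  expect_lt(abs(mean(tab$gsh_umol_per_gHb[tab$condition == "SL"]) - 3.4), 0.1)
})

test_that("generated tables satisfy the sample-table invariants", {
  for (s in 1:5) {
    tab <- generate_cohort(seed = s)
    expect_true(all(tab$gsh_umol_per_gHb > 0))
    expect_true(all(tab$gssg_umol_per_gHb > 0))
    expect_true(all(tab$so2_percent >= 0 & tab$so2_percent <= 100))
    expect_true(all(tab$hb_g_per_L > 0))
    ton <- generate_tonometry(tonometry_scenario(), seed = s)
    expect_true(all(ton$gsh_umol_per_gHb > 0))
  }
})

test_that("synthesis inhibition leaves the release curve unchanged by construction", {
  ctrl <- generate_tonometry(tonometry_scenario(mode = "control"), seed = 9)
  bso <- generate_tonometry(tonometry_scenario(mode = "BSO"), seed = 9)
  expect_identical(ctrl$gsh_umol_per_gHb, bso$gsh_umol_per_gHb)
})

test_that("thiol blockade abolishes the saturation dependence of free GSH", {
  sc <- tonometry_scenario(mode = "NEM",
                           so2_grid_percent = seq(98, 5, length.out = 40))
  nem <- generate_tonometry(sc, seed = 2)
  fit <- summary(lm(gsh_umol_per_gHb ~ so2_percent, data = nem))
  expect_gt(fit$coefficients["so2_percent", "Pr(>|t|)"], 0.01)
  expect_lt(mean(nem$gsh_umol_per_gHb), 0.6)
})

test_that("noiseless generator output closes the loop with every analysis stage", {
  # tonometry -> occupancy/baseline
  ton <- generate_tonometry(tonometry_scenario(noise_sd = 0), seed = 1)
  res <- run_tonometry_analysis(ton)
  expect_true(res$threshold$threshold_found)
  expect_equal(res$results$phi, 0.17, tolerance = 1e-6)
  expect_equal(res$results$baseline_umol_per_gHb, 2.5, tolerance = 1e-6)
  # titration -> one-site thermodynamics
  th <- itc_thermo(4, 5e5, -20)
  expect_identical(generate_itc(thermo = th, noise_sd_uJ = 0, seed = 1)$heat_uJ,
                   simulate_trace(itc_protocol(), th)$heat_uJ)
  # additions -> initial amount
  d <- generate_standard_additions(1.8, 3, n = 6, noise_sd = 0, seed = 1)
  expect_equal(standard_additions(d$added_umol, d$intensity)$m0_umol, 1.8,
               tolerance = 1e-10)
})
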