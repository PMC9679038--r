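test_that("thermodynamic decomposition obeys the Gibbs identities", {
  expect_equal(thermo_decompose(1, -10)$dG, 0)
  dec <- thermo_decompose(1 / 2e-6, -20, 298.15)
  expect_equal(dec$dG, -32.53, tolerance = 1e-3) # -RT ln(5e5), hand-computed
  expect_equal(dec$kd, 2e-6)
  same <- thermo_decompose(5e4, thermo_decompose(5e4, 0)$dG)
  expect_equal(same$TdS, 0, tolerance = 1e-12)
  expect_error(thermo_decompose(0, -10), "positive")
  th <- itc_thermo(4, 5e5, -20)
  expect_equal(th$dG, th$dH - th$TdS, tolerance = 1e-12)
  expect_equal(th$kd, 1 / th$ka)
})

test_that("simulated trace heats vanish with zero enthalpy and carry its sign", {
  pr <- itc_protocol()
  expect_true(all(simulate_trace(pr, itc_thermo(4, 5e5, 0))$heat_uJ == 0))
  expect_true(all(simulate_trace(pr, itc_thermo(4, 5e5, -20))$heat_uJ < 0))
  expect_true(all(simulate_trace(pr, itc_thermo(4, 5e5, 12))$heat_uJ > 0))
})

test_that("very tight binding gives the stoichiometric titration plateau", {
  pr <- itc_protocol()
  tr <- simulate_trace(pr, itc_thermo(4, 1e12, -20))
  moles_inj <- pr$injection_volumes_uL[1] * 1e-6 * pr$syringe_conc_mM * 1e-3
  expected_uJ <- -20 * 1000 * moles_inj * 1e6
  expect_equal(tr$heat_uJ[1:3], rep(expected_uJ, 3), tolerance = 0.02)
})

test_that("closed-form isotherm matches the brute-force equilibrium oracle", {
  pr <- itc_protocol()
  set.seed(42)
  for (i in 1:10) {
    n <- runif(1, 0.5, 4.5)
    kd <- 10^runif(1, -7, -4)
    dh <- runif(1, -40, 40)
    if (abs(dh) < 1) dh <- dh + 5
    got <- simulate_trace(pr, itc_thermo(n, 1 / kd, dh))$heat_uJ
    want <- oracle_trace_heats(pr, n, 1 / kd, dh)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("one-site fit is an exact inverse of the forward model", {
  pr <- itc_protocol()
  for (n in c(1, 2, 4)) {
    for (kd_uM in c(1, 5, 20, 100)) {
      tr <- simulate_trace(pr, itc_thermo(n, 1 / (kd_uM * 1e-6), -20))
      fit <- fit_one_site(tr, pr)
      expect_lt(abs(fit$thermo$n_sites - n) / n, 1e-3)
      expect_lt(abs(fit$thermo$kd * 1e6 - kd_uM) / kd_uM, 1e-3)
      expect_lt(abs(fit$thermo$dH - (-20)) / 20, 1e-3)
    }
  }
})

test_that("degenerate traces are flagged rather than silently fitted", {
  pr <- itc_protocol()
  zero <- simulate_trace(pr, itc_thermo(4, 5e5, 0))
  expect_error(fit_one_site(zero, pr), "zero")
  expect_error(fit_one_site(simulate_trace(pr, itc_thermo(4, 5e5, -20))[1:5, ],
                            pr), "at least 8")
  # ligand never approaches the stoichiometry: all heats identical
  weak_pr <- itc_protocol(syringe_conc_mM = 0.5)
  sat <- simulate_trace(weak_pr, itc_thermo(4, 1e12, -20))
  expect_warning(fit_one_site(sat, weak_pr), "saturated")
})

test_that("microcalorie conversion uses the thermochemical calorie", {
  expect_equal(ucal_to_uJ(1), 4.184)
  expect_equal(ucal_to_uJ(c(0, -2)), c(0, -8.368))
})
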