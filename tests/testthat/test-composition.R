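test_that("hemoglobin mass-to-molar conversion reproduces the reference values", {
  expect_lt(abs(hb_mass_to_molar(335, default_comp) - 5.23), 0.005)
  expect_identical(hb_mass_to_molar(0, default_comp), 0)
  expect_equal(hb_mass_to_molar(64, default_comp), 1.0)
  expect_equal(hb_mass_to_molar(100, default_comp), 1.5625)
  expect_error(hb_mass_to_molar(-1, default_comp), "non-negative")
})

test_that("mass-to-molar conversion round-trips through the molar mass", {
  set.seed(11)
  c_gL <- runif(50, 0, 400)
  back <- hb_mass_to_molar(c_gL, default_comp) * default_comp$hb_molar_mass / 1000
  expect_equal(back, c_gL, tolerance = 1e-12)
})

test_that("per-gram-Hb to cell-water conversion matches the worked values and is linear", {
  expect_lt(abs(per_gHb_to_cellwater(2.5, default_comp) - 1.23), 0.005)
  expect_lt(abs(per_gHb_to_cellwater(6.0, default_comp) - 2.96), 0.005)
  expect_identical(per_gHb_to_cellwater(0, default_comp), 0)
  set.seed(12)
  a <- runif(20, 0, 10)
  b <- runif(20, 0, 10)
  expect_equal(per_gHb_to_cellwater(a + b, default_comp),
               per_gHb_to_cellwater(a, default_comp) +
                 per_gHb_to_cellwater(b, default_comp),
               tolerance = 1e-12)
  expect_error(per_gHb_to_cellwater(-0.1, default_comp), "non-negative")
  # inverse
  expect_equal(cellwater_to_per_gHb(per_gHb_to_cellwater(a, default_comp),
                                    default_comp),
               a, tolerance = 1e-12)
})

test_that("release capacity and released fraction behave at the edges", {
  expect_identical(max_release_capacity(0, 2), 0)
  expect_equal(max_release_capacity(1.0, 4), 4.0)
  expect_error(max_release_capacity(5, 2.5), "integer")
  expect_identical(release_fraction(0, 10.46), 0)
  expect_equal(release_fraction(10.46, 10.46), 100)
  expect_error(release_fraction(1, 0), "positive")
  expect_warning(release_fraction(12, 10), "exceeds")
})

test_that("the four-step buffering-capacity chain reproduces the desk arithmetic", {
  hb <- hb_mass_to_molar(335, default_comp)
  baseline <- per_gHb_to_cellwater(2.5, default_comp)
  deoxy <- per_gHb_to_cellwater(6.0, default_comp)
  released <- deoxy - baseline
  capacity <- max_release_capacity(hb, 2)
  frac <- release_fraction(released, capacity)
  expect_equal(round(baseline, 2), 1.23)
  expect_equal(round(deoxy, 2), 2.96)
  expect_lt(abs(released - 1.73), 0.01) # 1.73 is a subtraction of rounded values
  expect_equal(round(capacity, 1), 10.5)
  expect_equal(round(frac, 1), 16.5)
})
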