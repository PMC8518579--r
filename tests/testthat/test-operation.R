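test_that("Tafel current clamps below the critical voltage", {
  expect_identical(tafel_current(0.8, ecomite), 0)
  expect_equal(tafel_current(1.0, ecomite), ecomite$tafel_a,
               tolerance = 1e-15)
  expect_equal(tafel_current(1.0 + ecomite$tafel_b, ecomite),
               ecomite$tafel_a * exp(1), tolerance = 1e-12)
})

test_that("effective voltage subtracts ohmic and electrolyte drops", {
  expect_equal(effective_voltage(1.3, 0, ecomite, 0.15), 1.3)
  # lead/electrode drop: 45 mV at 50 mA, 90 mV at 100 mA
  k_big <- 1e9   # suppress the electrolyte term
  expect_equal(1.3 - effective_voltage(1.3, 0.05, ecomite, k_big), 0.045,
               tolerance = 1e-6)
  expect_equal(1.3 - effective_voltage(1.3, 0.10, ecomite, k_big), 0.090,
               tolerance = 1e-6)
  # electrolyte drop: 6/0.15 * 0.05^2 = 0.10 V
  expect_equal(effective_voltage(1.3, 0.05, ecomite, 0.15),
               1.3 - 0.045 - 0.10, tolerance = 1e-12)
  expect_error(effective_voltage(0.2, 0.2, ecomite, 0.05), "exceed")
})

test_that("parasitic charge vanishes without a Tafel current", {
  spec0 <- cell_spec(tafel_a = 0)
  r <- redox_charge(1.3, 0.05, spec0, 0.15)
  expect_identical(r$q_redox_C, 0)
  # threshold below the critical voltage: clamped everywhere
  r2 <- redox_charge(0.9, 0.05, ecomite, 0.15)
  expect_identical(r2$q_redox_C, 0)
  expect_gt(r2$q_total_C, 0)
})

test_that("corrected efficiency scales by the parasitic fraction", {
  expect_equal(corrected_efficiency(0.45, 0, 1), 0.45)
  expect_equal(corrected_efficiency(0.45, 1, 1), 0)
  expect_equal(corrected_efficiency(0.45, 0.06, 1), 0.423,
               tolerance = 1e-12)
  expect_error(corrected_efficiency(0.5, 2, 1))
})

test_that("calibrated Tafel parameters give a smaller parasitic fraction at higher current", {
  kappa <- solve_solution_state(0.010, 8, ma,
                                "activity_corrected")$conductivity
  cal <- calibrate_tafel(ecomite, 1.3, 0.05, kappa, 0.06)
  expect_equal(redox_charge(1.3, 0.05, cal, kappa)$fraction, 0.06,
               tolerance = 1e-10)
  # same threshold traversed twice as fast: less charge lost above crit
  frac100 <- redox_charge(1.3, 0.10, cal, kappa)$fraction
  expect_lt(frac100, 0.06)
})

test_that("constant-current prediction reduces to the static case at I = 0", {
  spec0 <- cell_spec(tafel_a = 0)
  op <- operating_point(1.2, 0, feed_c_total = 0.005, feed_pH = 8)
  cc <- predict_constant_current(op, tbl1, ma, spec0)
  cv <- predict_cv_grid(8, 5, 1.2, tbl1, ma, spec0)
  expect_equal(cc$lambda, cv$lambda, tolerance = 1e-12)
  expect_equal(cc$lambda_corr, cc$lambda)
  expect_equal(cc$sac_eq_g, cv$sac_eq_g, tolerance = 1e-12)
  expect_equal(cc$sac_mol_g, cv$sac_mol_g, tolerance = 1e-12)
})

test_that("the Donnan potential of the reference constant-current run is ~0.97", {
  op <- operating_point(1.3, 0.05, feed_c_total = 0.010, feed_pH = 8)
  cc <- predict_constant_current(op, tbl1, ma, ecomite)
  expect_equal(cc$phi_D, 0.97, tolerance = 0.05 / 0.97)
  expect_lte(cc$lambda_corr, cc$lambda)
  expect_equal(cc$sac_eq_g, cc$lambda_corr * cc$sigma_eq_g,
               tolerance = 1e-15)
})

test_that("doubling the current strictly lowers the predicted SAC", {
  op50 <- operating_point(1.3, 0.05, feed_c_total = 0.010, feed_pH = 8)
  op100 <- operating_point(1.3, 0.10, feed_c_total = 0.010, feed_pH = 8)
  s50 <- predict_constant_current(op50, tbl1, ma, ecomite)
  s100 <- predict_constant_current(op100, tbl1, ma, ecomite)
  expect_lt(s100$sac_eq_g, s50$sac_eq_g)
  expect_lt(s100$dphi_eff_V, s50$dphi_eff_V)
})

test_that("coion-expulsion lag matches the reference 13 minutes", {
  p <- pfl(0.010, 8.5, tbl1, ma)
  tE <- lag_time(p, ecomite, 0.05)
  expect_equal(tE / 60, 13, tolerance = 1 / 13)
  expect_identical(lag_time(0, ecomite, 0.05), 0)
  expect_equal(lag_time(p, ecomite, 0.10), tE / 2, tolerance = 1e-12)
})

test_that("micropore pH estimates match the closed forms", {
  expect_equal(micropore_ph_shift(0.97), 0.97 / log(10), tolerance = 1e-15)
  expect_equal(micropore_ph_shift(0.97), 0.42, tolerance = 1e-2)
  expect_identical(micropore_ph_shift(0), 0)
  rb <- micropore_ratio_bound(0.6, 0.02)
  expect_equal(rb$ratio, 30, tolerance = 1e-12)
  expect_equal(rb$delta_pH, 1.477, tolerance = 1e-3)
})

test_that("energy cost reproduces the order-of-magnitude estimate", {
  ec <- energy_cost(86.2, 2, 0.25, 1.3, 0.1)
  expect_equal(ec$eur_per_h, 1.1, tolerance = 0.15)
  expect_equal(ec$eur_per_mol, 0.013, tolerance = 0.15)
  # exact against in-test arithmetic
  charge <- 86.2 * 2 * 96485.33212 / 0.25
  expect_equal(ec$eur_per_h, 0.5 * charge * 1.3 / 3.6e6 * 0.1,
               tolerance = 1e-12)
  expect_identical(energy_cost(86.2, 2, 0.25, 1.3, 0)$eur_per_h, 0)
  # cost per mol is inversely proportional to the charge efficiency
  expect_equal(energy_cost(86.2, 2, 0.125, 1.3, 0.1)$eur_per_mol,
               2 * ec$eur_per_mol, tolerance = 1e-12)
})
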