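ref_op <- operating_point(1.3, 0.05, flow_rate = 0.002,
                          feed_c_total = 0.010, feed_pH = 8)
ref_pred <- predict_constant_current(ref_op, tbl1, ma, ecomite)

test_that("synthesized trace closes the analysis loop at zero noise", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 4)
  res <- analyze_cycles(tr, ma, electrode_pair_mass = pair_mass(ecomite),
                        drop_cycles = 2)
  expect_equal(res$summary$sac_mol_g, ref_pred$sac_mol_g,
               tolerance = 0.01)
  expect_equal(res$summary$lambda_pct, ref_pred$lambda_corr * 100,
               tolerance = 0.02)
})

test_that("identical cycles give near-zero SAC spread in cyclic steady state", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 4)
  res <- analyze_cycles(tr, ma, electrode_pair_mass = pair_mass(ecomite),
                        drop_cycles = 0)
  expect_lt(sd(res$per_cycle$sac_mol_g) / mean(res$per_cycle$sac_mol_g),
            1e-6)
})

test_that("a full cycle conserves mass by construction", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 1)
  conc <- trace_to_concentrations(tr, ma)
  c0 <- attr(tr, "feed_c_total")
  net <- pracma::trapz(tr$time_s, tr$flow_L_min / 60 * (c0 - conc$c_total))
  adsorbed <- ref_pred$sac_mol_g * pair_mass(ecomite)
  expect_lt(abs(net) / adsorbed, 5e-3)
})

test_that("the effluent drop starts after the coion-expulsion lag", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 1,
                         dt_s = 5)
  conc <- trace_to_concentrations(tr, ma)
  c0 <- attr(tr, "feed_c_total")
  onset <- tr$time_s[min(which(conc$c_total < c0 * 0.999))]
  expect_equal(onset, ref_pred$t_E_s, tolerance = 0.05)
})

test_that("noisy traces still recover SAC within a few percent", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 4,
                         noise = 0.02, seed = 42)
  res <- analyze_cycles(tr, ma, electrode_pair_mass = pair_mass(ecomite),
                        drop_cycles = 2)
  expect_equal(res$summary$sac_mol_g, ref_pred$sac_mol_g,
               tolerance = 0.05)
})

test_that("step-shaped concentration profiles invert to step shapes", {
  ct <- c(rep(0.010, 5), rep(0.007, 5))
  kap <- vapply(ct, function(x)
    solve_solution_state(x, 8, ma)$conductivity, numeric(1))
  tr <- effluent_trace(seq_along(ct) * 10, kap, rep(8, 10), rep(0.002, 10),
                       rep(0.05, 10), 0.010, 8)
  conc <- trace_to_concentrations(tr, ma)
  expect_true(all(conc$converged))
  expect_equal(conc$c_total, ct, tolerance = 5e-3)
})

test_that("rectangular depletion integrates to the hand value", {
  n <- 181
  tr <- effluent_trace(seq(0, 1800, length.out = n), rep(0.2, n),
                       rep(8, n), rep(0.002, n), rep(0.05, n), 0.010, 8)
  c_series <- rep(0.009, n)   # constant 1 mM depletion for 30 min
  sac <- integrate_sac(c_series, tr, 3.32, seq_len(n))
  expect_equal(sac, 0.001 * 0.002 / 60 * 1800 / 3.32, tolerance = 1e-12)
  expect_equal(sac, 1.807e-5, tolerance = 1e-3)
  # no depletion, no capacity; half the mass doubles the value
  expect_equal(integrate_sac(rep(0.010, n), tr, 3.32, seq_len(n)), 0)
  expect_equal(integrate_sac(c_series, tr, 1.66, seq_len(n)), 2 * sac,
               tolerance = 1e-12)
  expect_error(integrate_sac(c_series, tr, 3.32, integer(0)), "empty")
})

test_that("experimental charge efficiency matches the arithmetic oracle", {
  expect_equal(charge_efficiency_exp(1.807e-5, 0, 120, 3.32), 9.65,
               tolerance = 1e-3)
  # all-monovalent vs all-divalent at equal SAC: exactly half
  expect_equal(charge_efficiency_exp(1e-5, 1, 100, 3.32),
               charge_efficiency_exp(1e-5, 0, 100, 3.32) / 2,
               tolerance = 1e-12)
  expect_equal(charge_efficiency_exp(0, 0.5, 100, 3.32), 0)
  expect_error(charge_efficiency_exp(1e-5, 0, 0, 3.32))
})

test_that("cycle detection follows the current program", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 6)
  cyc <- detect_cycles(tr)
  expect_equal(nrow(cyc), 6)
  expect_true(all(tr$current_A[cyc$ads_start] > 0))
  expect_true(all(tr$current_A[cyc$des_start[!is.na(cyc$des_start)]] == 0))
  tr0 <- tr
  tr0$current_A[] <- 0
  expect_error(detect_cycles(tr0), "all zero")
})

test_that("trace io round-trips including the feed attributes", {
  tr <- synthesize_trace(ref_op, ref_pred, ma, ecomite, n_cycles = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effluent_trace(tr, f)
  tr2 <- read_effluent_trace(f)
  expect_equal(attr(tr2, "feed_c_total"), attr(tr, "feed_c_total"))
  expect_equal(tr2$conductivity_S_m, tr$conductivity_S_m, tolerance = 1e-8)
})
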