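test_that("micropore Boltzmann enrichment behaves as expected", {
  expect_equal(micropore_concentration(0.01, 1, 0, 0), 0.01)
  # divalent anion at phi_D = 0.5: e^1 enrichment
  expect_equal(micropore_concentration(0.001, -2, 0.5, 0), 0.001 * exp(1),
               tolerance = 1e-12)
  # attraction exactly cancelling electrostatic repulsion
  expect_equal(micropore_concentration(0.004, 1, 0.5, 0.5), 0.004,
               tolerance = 1e-12)
})

test_that("Donnan potential and micropore charge are exact inverses", {
  expect_identical(phi_from_charge(0, 0.01), 0)
  expect_equal(phi_from_charge(0.02, 0.01), asinh(1), tolerance = 1e-15)
  set.seed(3)
  phi <- runif(20, 0, 3)
  c0 <- runif(20, 1e-4, 0.5)
  expect_equal(phi_from_charge(2 * c0 * sinh(phi), c0), phi,
               tolerance = 1e-12)
  expect_error(phi_from_charge(0.01, 0), "c0_mi")
})

test_that("micropore charge bookkeeping is self-consistent", {
  # counterion gain plus coion loss equals 2 c0_mi sinh(phi) for a 1:1 salt
  set.seed(4)
  for (i in 1:10) {
    phi <- runif(1, 0, 2); mu <- runif(1, -1, 1); c_ma <- runif(1, 1e-3, 0.1)
    c0_mi <- micropore_concentration(c_ma, 0, 0, mu)
    counter <- micropore_concentration(c_ma, -1, phi, mu)
    co <- micropore_concentration(c_ma, +1, phi, mu)
    expect_equal((counter - c0_mi) + (c0_mi - co), 2 * c0_mi * sinh(phi),
                 tolerance = 1e-12)
  }
})

test_that("charge efficiency obeys the tanh-arcsinh identity", {
  expect_identical(charge_efficiency_from_phi(0), 0)
  expect_equal(charge_efficiency_from_phi(0.97), tanh(0.485),
               tolerance = 1e-15)
  # tanh(asinh(x)/2) = x / (1 + sqrt(1 + x^2)) to machine precision
  x <- c(1e-6, 0.01, 0.5, 1, 2, 10, 100)
  expect_equal(tanh(asinh(x) / 2), x / (1 + sqrt(1 + x^2)),
               tolerance = 1e-12)
  expect_equal(charge_efficiency_from_phi(asinh(1)), 1 / (1 + sqrt(2)),
               tolerance = 1e-12)
})

test_that("specific charge is linear in voltage and hits 0.14 meq/g at 1.2 V", {
  expect_equal(specific_charge(1.2, ecomite), 1.399e-4, tolerance = 1e-3)
  expect_identical(specific_charge(0, ecomite), 0)
  expect_equal(specific_charge(2.4, ecomite), 2 * specific_charge(1.2, ecomite),
               tolerance = 1e-15)
})

test_that("static charge efficiency reproduces the pH 4 / pH 8 contrast", {
  lam4 <- charge_efficiency_static(1.2, pfl(0.005, 4, tbl1, ma), ecomite)
  lam8 <- charge_efficiency_static(1.2, pfl(0.005, 8, tbl1, ma), ecomite)
  expect_equal(lam4$lambda * 100, 42, tolerance = 3 / 42)
  expect_equal(lam8$lambda * 100, 63, tolerance = 3 / 63)
  expect_gt(lam8$lambda, lam4$lambda)
  # electrode basis skips the halving: same answer for pfl/2 on pair basis
  expect_equal(charge_efficiency_static(1.2, 0.2, ecomite, "pair")$lambda,
               charge_efficiency_static(1.2, 0.1, ecomite,
                                        "electrode")$lambda,
               tolerance = 1e-15)
})

test_that("charge efficiency limits: high PFL -> 0, zero PFL -> 1", {
  expect_lt(charge_efficiency_static(1.2, 1e6, ecomite)$lambda, 1e-6)
  expect_warning(res <- charge_efficiency_static(1.2, 0, ecomite),
                 "limit")
  expect_identical(res$lambda, 1)
})

test_that("constant-voltage grid is definitionally and monotonically sound", {
  g <- predict_cv_grid(seq(4, 10, 0.25), 5, c(0.6, 0.9, 1.2), tbl1, ma,
                       ecomite)
  expect_equal(g$sac_eq_g, g$lambda * g$sigma_eq_g, tolerance = 1e-15)
  expect_true(all(g$sac_mol_g <= g$sac_eq_g + 1e-15))
  # lambda increases with voltage at fixed (pH, c)
  for (p in unique(g$pH)) {
    sub <- g[g$pH == p, ]
    expect_true(all(diff(sub$lambda[order(sub$dphi_cell_V)]) > 0))
  }
  # the efficiency transition is centered near pKa2
  sub <- g[g$dphi_cell_V == 1.2, ]
  dldph <- diff(sub$lambda) / diff(sub$pH)
  center <- sub$pH[which.max(dldph)]
  expect_gt(center, 5.5)
  expect_lt(center, 7.0)
})
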