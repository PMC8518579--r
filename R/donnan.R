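#' Electrode pair and cell electrical parameters
#'
#' Collects the material and setup constants of a two-electrode CDI cell:
#' specific capacitance, electrode masses, micropore volume, ohmic setup
#' resistance, electrolyte cell constant, Tafel parameters of the parasitic
#' redox current and the critical voltage above which it sets in. Defaults
#' are the Ecomite-U cell values.
#'
#' The Tafel defaults (`tafel_a` = 1 mA, `tafel_b` = 0.12 V) are generic
#' placeholders; calibrate them against a measured parasitic charge
#' fraction with [calibrate_tafel()].
#'
#' @param Cg Specific capacitance in F/g.
#' @param electrode_mass_each Mass of one electrode in g.
#' @param n_electrodes Number of electrodes (2).
#' @param vm Micropore volume in cm^3/g.
#' @param R_setup Ohmic resistance of leads + electrodes in Ohm.
#' @param k_cell Electrolyte cell constant in (A m)^-1.
#' @param tafel_a Tafel pre-factor in A.
#' @param tafel_b Tafel slope in V.
#' @param dphi_crit Cell voltage in V above which parasitic currents flow.
#' @param mu_att Dimensionless chemical attraction term of the modified
#'   Donnan model (used for micropore bookkeeping, not in the PFL-based
#'   charge-efficiency predictions).
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(Cg = 45, electrode_mass_each = 1.66, n_electrodes = 2L,
                      vm = 0.62, R_setup = 0.9, k_cell = 6,
                      tafel_a = 0.001, tafel_b = 0.12, dphi_crit = 1.0,
                      mu_att = 0) {
  stopifnot(Cg > 0, electrode_mass_each > 0, vm > 0, R_setup > 0,
            k_cell > 0, tafel_a >= 0, tafel_b > 0, dphi_crit > 0)
  structure(list(Cg = Cg, electrode_mass_each = electrode_mass_each,
                 n_electrodes = as.integer(n_electrodes), vm = vm,
                 R_setup = R_setup, k_cell = k_cell,
                 tafel_a = tafel_a, tafel_b = tafel_b,
                 dphi_crit = dphi_crit, mu_att = mu_att),
            class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf(paste0("<cell_spec> Cg %.4g F/g, %d x %.3g g electrodes, ",
                     "vm %.3g cm^3/g\n  R_setup %.3g Ohm, k_cell %.3g ",
                     "(A m)^-1, Tafel a %.3g A / b %.3g V above %.3g V\n"),
              x$Cg, x$n_electrodes, x$electrode_mass_each, x$vm, x$R_setup,
              x$k_cell, x$tafel_a, x$tafel_b, x$dphi_crit))
  invisible(x)
}

#' Total electrode-pair mass
#'
#' @param spec A [cell_spec()].
#' @return Mass of all electrodes in g.
#' @export
pair_mass <- function(spec) spec$n_electrodes * spec$electrode_mass_each

#' Micropore concentration from the modified Donnan model
#'
#' `c_mi = c_ma * exp(-z * phi_D + mu_att)`: Boltzmann enrichment or
#' depletion of an ion of charge `z` at dimensionless Donnan potential
#' `phi_D`, plus a constant chemical attraction term.
#'
#' @param c_ma Macropore (bulk) concentration, mol/L, >= 0.
#' @param z Ion charge (signed integer).
#' @param phi_D Dimensionless Donnan potential.
#' @param mu_att Dimensionless attraction term.
#' @return Micropore concentration in mol/L.
#' @export
micropore_concentration <- function(c_ma, z, phi_D, mu_att = 0) {
  stopifnot(all(c_ma >= 0))
  c_ma * exp(-z * phi_D + mu_att)
}

#' Donnan potential from the micropore charge density
#'
#' Inverts `delta_c_mi = 2 * c0_mi * sinh(phi_D)` to
#' `phi_D = asinh(delta_c_mi / (2 c0_mi))`.
#'
#' @param delta_c_mi Change in micropore ionic charge density, mol/L.
#' @param c0_mi Initial (equilibrated, zero-voltage) micropore
#'   concentration, mol/L, > 0.
#' @return Dimensionless Donnan potential.
#' @export
phi_from_charge <- function(delta_c_mi, c0_mi) {
  if (any(c0_mi <= 0)) stop("c0_mi must be > 0")
  asinh(delta_c_mi / (2 * c0_mi))
}

#' Charge efficiency from the Donnan potential
#'
#' `Lambda = tanh(phi_D / 2)`: strictly increasing, 0 at zero potential,
#' approaching 1 for strongly charged micropores.
#'
#' @param phi_D Dimensionless Donnan potential, >= 0.
#' @return Charge efficiency in `[0, 1)`.
#' @export
charge_efficiency_from_phi <- function(phi_D) {
  stopifnot(all(phi_D >= 0))
  tanh(phi_D / 2)
}

#' Specific charge stored at a given cell voltage
#'
#' Constant-capacitance estimate of the charge transferred per gram of
#' electrode pair: `Sigma = Cg * dphi_cell / (4 * F)` in eq/g. At 1.2 V and
#' 45 F/g this is 1.4e-4 eq/g, i.e. ~0.14 meq/g - the hypothetical maximum
#' electrosorption capacity of the cell.
#'
#' @param dphi_cell Cell voltage in V, >= 0. Vectorized.
#' @param spec A [cell_spec()].
#' @return Specific charge in eq per gram of electrode pair.
#' @export
specific_charge <- function(dphi_cell, spec) {
  stopifnot(all(dphi_cell >= 0))
  spec$Cg * dphi_cell / (4 * .FARADAY)
}

#' Equilibrium charge efficiency at constant voltage
#'
#' The explicit closed form coupling the charge efficiency to the
#' potential-free loading:
#' `Lambda = tanh(0.5 * asinh(Sigma / PFL_eff))` with
#' `Sigma = Cg * dphi_cell / (4 F)`.
#'
#' The potential-free loading is measured per gram of electrode *pair*
#' (batch experiments use the total mass), while the coion reservoir that
#' opposes charging sits in a single electrode. With the default
#' `basis = "pair"` the effective loading is therefore `pfl / 2` (converted
#' to eq/g); pass `basis = "electrode"` if `pfl` is already per gram of a
#' single electrode.
#'
#' @param dphi_cell Cell voltage in V.
#' @param pfl Potential-free loading in meq/g (pair basis by default).
#' @param spec A [cell_spec()].
#' @param basis `"pair"` (default) or `"electrode"`; see Details.
#' @return A list with `phi_D` (the internal hypothetical maximum Donnan
#'   potential) and `lambda` (charge efficiency, 0..1), each vectorized.
#' @examples
#' p <- pfl(0.005, 4, maleic_ecomite_parameters(), maleic_acid())
#' charge_efficiency_static(1.2, p, cell_spec())$lambda  # ~0.44
#' @export
charge_efficiency_static <- function(dphi_cell, pfl, spec,
                                     basis = c("pair", "electrode")) {
  basis <- match.arg(basis)
  stopifnot(all(pfl >= 0))
  pfl_eff <- pfl / 1000 / if (basis == "pair") 2 else 1  # eq/g
  sigma <- specific_charge(dphi_cell, spec)
  if (any(pfl_eff == 0)) {
    warning("pfl = 0: charge efficiency reported at its limit of 1")
  }
  phi_D <- ifelse(pfl_eff > 0, asinh(sigma / pfl_eff), Inf)
  list(phi_D = phi_D, lambda = tanh(phi_D / 2))
}

#' Constant-voltage equilibrium prediction grid
#'
#' Evaluates the full equilibrium chain - speciation, PFL, charge
#' efficiency, salt adsorption capacity - over the cross product of pH,
#' concentration and cell-voltage vectors. These are maximum (idealized)
#' values: full equilibration, no parasitic currents, no voltage drops.
#'
#' `sac_eq = lambda * sigma` (eq/g) and `sac_mol = sac_eq / z_mean` with
#' `z_mean = alpha + 2 (1 - alpha)`, `alpha` the monovalent fraction of the
#' dissolved charged acid.
#'
#' @param pH,c_total_mM,dphi_cell_V Vectors spanning the grid.
#' @param params A [moreau_parameters()].
#' @param acid An [acid_definition()].
#' @param spec A [cell_spec()].
#' @param basis Mass-basis convention, see [charge_efficiency_static()].
#' @return A data.frame with one row per grid point: `pH`, `c_total_mM`,
#'   `dphi_cell_V`, `pfl_meq_g`, `phi_D`, `lambda`, `sigma_eq_g`,
#'   `sac_eq_g`, `sac_mol_g`, `z_mean`.
#' @export
predict_cv_grid <- function(pH, c_total_mM, dphi_cell_V, params, acid, spec,
                            basis = "pair") {
  g <- expand.grid(pH = pH, c_total_mM = c_total_mM,
                   dphi_cell_V = dphi_cell_V, KEEP.OUT.ATTRS = FALSE)
  fr <- species_fractions(g$pH, acid)
  ct <- g$c_total_mM / 1000
  q <- moreau_loadings(ct * fr[, "HA"], ct * fr[, "A2"], params)
  eff <- charge_efficiency_static(g$dphi_cell_V, q$pfl, spec, basis)
  sigma <- specific_charge(g$dphi_cell_V, spec)
  alpha <- fr[, "HA"] / (fr[, "HA"] + fr[, "A2"])
  z_mean <- alpha + 2 * (1 - alpha)
  data.frame(g, pfl_meq_g = q$pfl, phi_D = eff$phi_D, lambda = eff$lambda,
             sigma_eq_g = sigma, sac_eq_g = eff$lambda * sigma,
             sac_mol_g = eff$lambda * sigma / z_mean, z_mean = z_mean)
}
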