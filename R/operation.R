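#' Operating point of a CDI run
#'
#' @param dphi_pot Threshold (constant-current) or set (constant-voltage)
#'   cell voltage in V, > 0.
#' @param current Applied current in A; 0 selects constant-voltage
#'   behaviour.
#' @param flow_rate Feed flow rate in L/min.
#' @param feed_c_total Total acid concentration of the feed in mol/L.
#' @param feed_pH Feed pH.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(dphi_pot, current = 0, flow_rate = 0.002,
                            feed_c_total, feed_pH) {
  stopifnot(dphi_pot > 0, current >= 0, flow_rate >= 0, feed_c_total >= 0)
  structure(list(mode = if (current > 0) "constant_current"
                 else "constant_voltage",
                 dphi_pot = dphi_pot, current = current,
                 flow_rate = flow_rate, feed_c_total = feed_c_total,
                 feed_pH = feed_pH),
            class = "operating_point")
}

#' Parasitic (Tafel) redox current
#'
#' `I_redox = a * exp((dphi_cell - dphi_crit) / b)` above the critical cell
#' voltage, clamped to zero below it.
#'
#' @param dphi_cell Cell voltage in V, vectorized.
#' @param spec A [cell_spec()] supplying `tafel_a`, `tafel_b`, `dphi_crit`.
#' @return Parasitic current in A.
#' @export
tafel_current <- function(dphi_cell, spec) {
  stopifnot(all(dphi_cell >= 0), spec$tafel_b != 0)
  ifelse(dphi_cell >= spec$dphi_crit,
         spec$tafel_a * exp((dphi_cell - spec$dphi_crit) / spec$tafel_b),
         0)
}

#' Effective charging voltage under constant current
#'
#' Subtracts the ohmic drop of leads/electrodes and the electrolyte drop
#' from the potentiostat threshold:
#' `dphi_eff = dphi_pot - R_setup * I - (k_cell / kappa) * I^2`.
#'
#' @param dphi_pot Threshold voltage in V.
#' @param current Applied current in A.
#' @param spec A [cell_spec()].
#' @param kappa Electrolyte conductivity in S/m, > 0.
#' @return Effective voltage in V; errors if the drops consume the whole
#'   threshold.
#' @export
effective_voltage <- function(dphi_pot, current, spec, kappa) {
  stopifnot(kappa > 0, current >= 0)
  v <- dphi_pot - spec$R_setup * current -
    spec$k_cell / kappa * current^2
  if (any(v <= 0))
    stop("voltage drops exceed the threshold: no effective charging voltage")
  v
}

#' Parasitic charge over a constant-current charging ramp
#'
#' Integrates the Tafel current along the linear charging ramp
#' `dphi_cell(t) = I R_setup + (k_cell/kappa) I^2 + 4 F Sigma(t) / Cg` with
#' `Sigma(t) = I t / (F m_pair)`, from t = 0 until the cell voltage reaches
#' `dphi_pot`, by the trapezoidal rule.
#'
#' @param dphi_pot Threshold voltage in V.
#' @param current Applied current in A, > 0.
#' @param spec A [cell_spec()].
#' @param kappa Electrolyte conductivity in S/m.
#' @param n_steps Number of trapezoid steps (>= 200).
#' @return A list: `q_redox_C` and `q_total_C` (C), `fraction`
#'   (`q_redox / q_total`), `t_end_s` (ramp duration, s).
#' @export
redox_charge <- function(dphi_pot, current, spec, kappa, n_steps = 400L) {
  stopifnot(current > 0, n_steps >= 200L)
  m <- pair_mass(spec)
  dphi_eff <- effective_voltage(dphi_pot, current, spec, kappa)
  drops <- dphi_pot - dphi_eff
  # ramp ends when the capacitive part reaches dphi_eff
  t_end <- spec$Cg * dphi_eff * m / (4 * current)
  tt <- seq(0, t_end, length.out = n_steps + 1L)
  dphi_cell <- drops + 4 * current * tt / (spec$Cg * m)
  i_redox <- tafel_current(dphi_cell, spec)
  q_redox <- pracma::trapz(tt, i_redox)
  q_total <- current * t_end
  list(q_redox_C = q_redox, q_total_C = q_total,
       fraction = q_redox / q_total, t_end_s = t_end)
}

#' Charge efficiency corrected for parasitic charge
#'
#' `Lambda_corr = Lambda * (1 - Q_redox / Sigma_total)`.
#'
#' @param lambda Uncorrected charge efficiency.
#' @param q_redox Parasitic charge (same unit as `sigma_total`).
#' @param sigma_total Total supplied charge, > 0.
#' @return Corrected charge efficiency.
#' @export
corrected_efficiency <- function(lambda, q_redox, sigma_total) {
  stopifnot(sigma_total > 0, q_redox >= 0, q_redox <= sigma_total)
  lambda * (1 - q_redox / sigma_total)
}

#' Calibrate the Tafel pre-factor to a known parasitic charge fraction
#'
#' The parasitic charge is proportional to `tafel_a`, so a single measured
#' charge fraction at one operating point fixes it:
#' `a_new = a * target / fraction(a)`.
#'
#' @param spec A [cell_spec()].
#' @param dphi_pot,current,kappa Operating point of the calibration
#'   measurement.
#' @param target_fraction Measured `Q_redox / Q_total`.
#' @return The `cell_spec` with `tafel_a` rescaled.
#' @export
calibrate_tafel <- function(spec, dphi_pot, current, kappa,
                            target_fraction) {
  stopifnot(target_fraction >= 0)
  base <- redox_charge(dphi_pot, current, spec, kappa)
  if (base$fraction == 0)
    stop("cell voltage never exceeds dphi_crit: cannot calibrate")
  spec$tafel_a <- spec$tafel_a * target_fraction / base$fraction
  spec
}

#' Coion-expulsion lag time
#'
#' Time until the supplied charge equals the pre-loaded coion equivalents
#' that must be expelled before net adsorption shows in the effluent:
#' `t_E = PFL_eff * m_pair * F / I` with `PFL_eff = pfl / 2` on the pair
#' basis (equivalently, `pfl` times the single-electrode mass).
#'
#' @param pfl Potential-free loading in meq/g (electrode-pair basis).
#' @param spec A [cell_spec()].
#' @param current Applied current in A, > 0.
#' @return Lag time in seconds.
#' @examples
#' p <- pfl(0.010, 8.5, maleic_ecomite_parameters(), maleic_acid())
#' lag_time(p, cell_spec(), 0.05) / 60   # ~12.8 min
#' @export
lag_time <- function(pfl, spec, current) {
  stopifnot(current > 0, all(pfl >= 0))
  (pfl / 1000 / 2) * pair_mass(spec) * .FARADAY / current
}

#' Micropore pH shift implied by the Donnan potential
#'
#' The same Donnan potential applies to every ionic species, so the H+
#' enrichment in the micropores is `exp(phi_D)`, i.e. a pH shift of
#' `phi_D * log10(e) = phi_D / ln(10)`.
#'
#' @param phi_D Dimensionless Donnan potential.
#' @return pH shift between micropores and bulk (pH units).
#' @export
micropore_ph_shift <- function(phi_D) {
  phi_D / log(10)
}

#' Upper bound on the micropore/bulk H+ ratio
#'
#' Bounds the H+ enrichment by the enrichment of the most concentrated
#' inert cation: `ratio = c_mi_max / c_feed`, a pH difference of
#' `log10(ratio)`.
#'
#' @param c_mi_max Maximum micropore ion concentration, mol/L.
#' @param c_feed Feed (bulk) concentration of the same ion, mol/L.
#' @return A list with `ratio` and `delta_pH`.
#' @export
micropore_ratio_bound <- function(c_mi_max, c_feed) {
  stopifnot(c_mi_max > 0, c_feed > 0)
  r <- c_mi_max / c_feed
  list(ratio = r, delta_pH = log10(r))
}

#' Constant-current performance prediction
#'
#' Full prediction chain for a constant-current CDI step: feed speciation
#' and conductivity, effective voltage (ohmic and electrolyte drops),
#' specific charge, PFL-limited charge efficiency, Tafel parasitic-charge
#' correction, salt adsorption capacity and coion-expulsion lag time.
#' With `current = 0` the drops and the parasitic correction vanish and the
#' result equals the corresponding constant-voltage equilibrium row.
#'
#' @param op An [operating_point()].
#' @param params A [moreau_parameters()].
#' @param acid An [acid_definition()].
#' @param spec A [cell_spec()].
#' @param speciation_mode Mode for speciation/PFL (default `"ideal"`).
#' @param conductivity_mode Mode for the feed conductivity entering the
#'   electrolyte drop (default `"activity_corrected"`, the Davies-corrected
#'   conductance).
#' @param kappa Optional user-supplied conductivity in S/m overriding the
#'   feed-state value.
#' @param basis Mass-basis convention, see [charge_efficiency_static()].
#' @return A one-row data.frame: `pfl_meq_g`, `kappa_S_m`, `dphi_eff_V`,
#'   `sigma_eq_g`, `phi_D`, `lambda`, `q_redox_fraction`, `lambda_corr`,
#'   `sac_eq_g`, `sac_mol_g`, `z_mean`, `t_E_s`.
#' @export
predict_constant_current <- function(op, params, acid, spec,
                                     speciation_mode = "ideal",
                                     conductivity_mode = "activity_corrected",
                                     kappa = NULL, basis = "pair") {
  stopifnot(inherits(op, "operating_point"))
  feed <- solve_solution_state(op$feed_c_total, op$feed_pH, acid,
                               conductivity_mode)
  if (is.null(kappa)) kappa <- feed$conductivity
  p <- pfl(op$feed_c_total, op$feed_pH, params, acid, speciation_mode)

  if (op$current > 0) {
    dphi_eff <- effective_voltage(op$dphi_pot, op$current, spec, kappa)
    redox <- redox_charge(op$dphi_pot, op$current, spec, kappa)
    q_frac <- redox$fraction
    t_E <- lag_time(p, spec, op$current)
  } else {
    dphi_eff <- op$dphi_pot
    q_frac <- 0
    t_E <- NA_real_
  }
  sigma <- specific_charge(dphi_eff, spec)
  eff <- charge_efficiency_static(dphi_eff, p, spec, basis)
  lambda_corr <- eff$lambda * (1 - q_frac)
  # z_mean from the ideal speciation used for the isotherm
  fr <- species_fractions(op$feed_pH, acid, speciation_mode,
                          feed$ionic_strength)
  alpha <- fr[[1, "HA"]] / (fr[[1, "HA"]] + fr[[1, "A2"]])
  z_mean <- alpha + 2 * (1 - alpha)
  data.frame(pfl_meq_g = p, kappa_S_m = kappa, dphi_eff_V = dphi_eff,
             sigma_eq_g = sigma, phi_D = eff$phi_D, lambda = eff$lambda,
             q_redox_fraction = q_frac, lambda_corr = lambda_corr,
             sac_eq_g = lambda_corr * sigma,
             sac_mol_g = lambda_corr * sigma / z_mean,
             z_mean = z_mean, t_E_s = t_E)
}

#' Order-of-magnitude energy cost of CDI recovery
#'
#' Charge demand `rate * z_mean * F / lambda` per hour, energy at the
#' capacitor-average charging voltage `dphi_max / 2`, priced at the given
#' electricity tariff. A deliberately coarse operating-cost estimate
#' (no capital or replacement costs).
#'
#' @param production_rate_mol_h Product stream to be captured, mol/h.
#' @param z_mean Average charge per molecule, eq/mol.
#' @param lambda Charge efficiency (0..1], > 0.
#' @param dphi_max Maximum cell voltage in V.
#' @param electricity_price Price in EUR/kWh.
#' @param molar_mass Product molar mass in g/mol (for the per-kg figure).
#' @return A list: `eur_per_h`, `eur_per_mol`, `eur_per_kg`,
#'   `energy_kwh_per_h`, and the `assumption` string recording the
#'   half-voltage energy model.
#' @export
energy_cost <- function(production_rate_mol_h, z_mean, lambda, dphi_max,
                        electricity_price = 0.1, molar_mass = 116.07) {
  stopifnot(lambda > 0, production_rate_mol_h >= 0, dphi_max > 0)
  charge_C_h <- production_rate_mol_h * z_mean * .FARADAY / lambda
  energy_kwh_h <- 0.5 * charge_C_h * dphi_max / 3.6e6
  eur_h <- energy_kwh_h * electricity_price
  list(eur_per_h = eur_h,
       eur_per_mol = if (production_rate_mol_h > 0)
         eur_h / production_rate_mol_h else 0,
       eur_per_kg = if (production_rate_mol_h > 0)
         eur_h / (production_rate_mol_h * molar_mass / 1000) else 0,
       energy_kwh_per_h = energy_kwh_h,
       assumption = "energy = 0.5 * charge * dphi_max (capacitor-average charging voltage)")
}
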