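#' Load a run configuration
#'
#' Reads a YAML configuration with sections `acid`, `cell`, `isotherm`,
#' `ga` and `run` (seed and mode flags) and builds the corresponding
#' package objects. All quantities carry explicit units in their key names
#' (`pKa1`, `molar_mass_g_mol`, `lambda0_S_cm2_mol`, `Cg_F_g`, ...). The
#' shipped default configuration holds the maleic-acid / Ecomite-U values,
#' see [default_config_path()].
#'
#' @param path Path to the YAML file.
#' @return A list of class `run_config` with elements `acid`
#'   ([acid_definition()]), `cell` ([cell_spec()]), `isotherm`
#'   ([moreau_parameters()]), `ga` ([ga_config()]), `seed`,
#'   `speciation_mode`, `conductivity_mode`, `basis`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (s in c("acid", "cell", "isotherm"))
    if (is.null(y[[s]])) stop("config section missing: ", s)

  a <- y$acid
  acid <- acid_definition(
    name = a$name, pKa1 = a$pKa1, pKa2 = a$pKa2,
    molar_mass = a$molar_mass_g_mol,
    lambda0 = unlist(a$lambda0_S_cm2_mol))

  ce <- y$cell
  cell <- cell_spec(
    Cg = ce$Cg_F_g, electrode_mass_each = ce$electrode_mass_each_g,
    vm = ce$vm_cm3_g, R_setup = ce$R_setup_ohm,
    k_cell = ce$k_cell_per_A_m, tafel_a = ce$tafel_a_A,
    tafel_b = ce$tafel_b_V, dphi_crit = ce$dphi_crit_V,
    mu_att = if (is.null(ce$mu_att)) 0 else ce$mu_att)

  iso <- y$isotherm
  params <- moreau_parameters(
    K_A = iso$K_A_L_mol, K_B = iso$K_B_L_mol, q_max = iso$q_max_mmol_g,
    U_AA = iso$U_AA_kJ_mol, U_AB = iso$U_AB_kJ_mol,
    U_BB = iso$U_BB_kJ_mol,
    temperature = if (is.null(iso$temperature_K)) 298.15
    else iso$temperature_K)

  run <- if (is.null(y$run)) list() else y$run
  gy <- if (is.null(y$ga)) list() else y$ga
  ga <- ga_config(
    max_iterations = if (is.null(gy$max_iterations)) 20000L
    else gy$max_iterations,
    n_restarts = if (is.null(gy$n_restarts)) 10L else gy$n_restarts,
    mutation_rate = if (is.null(gy$mutation_rate)) 0.2
    else gy$mutation_rate,
    seed = if (is.null(run$seed)) 1L else run$seed)

  structure(list(acid = acid, cell = cell, isotherm = params, ga = ga,
                 seed = if (is.null(run$seed)) 1L else as.integer(run$seed),
                 speciation_mode = if (is.null(run$speciation_mode)) "ideal"
                 else run$speciation_mode,
                 conductivity_mode = if (is.null(run$conductivity_mode))
                   "activity_corrected" else run$conductivity_mode,
                 basis = if (is.null(run$basis)) "pair" else run$basis,
                 path = normalizePath(path)),
            class = "run_config")
}

#' Path to the shipped default configuration
#'
#' The maleic acid / Ecomite-U cell parameter set used throughout the
#' package examples.
#'
#' @return File path of the installed YAML config.
#' @export
default_config_path <- function() {
  system.file("extdata", "maleic_ecomite.yaml", package = "cdisorb",
              mustWork = TRUE)
}
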