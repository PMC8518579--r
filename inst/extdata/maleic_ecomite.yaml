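# Maleic acid on the Ecomite-U CDI cell: default parameter set.
acid:
  name: maleic acid
  pKa1: 1.92
  pKa2: 6.23
  molar_mass_g_mol: 116.07
  lambda0_S_cm2_mol:        # limiting molar conductivities
    Na: 50.11
    H: 349.8
    OH: 198.0
    HA: 41.0                # hydrogen maleate, estimate (cf. hydrogen oxalate 40.2)
    A2: 120.0               # maleate dianion, estimate (cf. fumarate ~124)

cell:
  Cg_F_g: 45.0
  electrode_mass_each_g: 1.66
  vm_cm3_g: 0.62
  R_setup_ohm: 0.9
  k_cell_per_A_m: 6.0
  tafel_a_A: 0.001          # placeholder; calibrate against a measured charge fraction
  tafel_b_V: 0.12
  dphi_crit_V: 1.0
  mu_att: 0.0

isotherm:                   # fitted Moreau parameters (restart means)
  K_A_L_mol: 23.4
  K_B_L_mol: 5.3
  q_max_mmol_g: 1.23
  U_AA_kJ_mol: -0.36
  U_AB_kJ_mol: 29.9
  U_BB_kJ_mol: 3.04
  temperature_K: 298.15

ga:
  max_iterations: 20000
  n_restarts: 10
  mutation_rate: 0.2

run:
  seed: 1
  speciation_mode: ideal
  conductivity_mode: activity_corrected
  basis: pair               # PFL measured per gram of electrode pair
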