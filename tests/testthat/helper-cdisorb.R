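# shared fixtures: the maleic acid / Ecomite-U reference system
ma <- maleic_acid()
ecomite <- cell_spec()
tbl1 <- maleic_ecomite_parameters()

# small in-bounds random Moreau parameter set (for property tests)
random_params <- function() {
  moreau_parameters(K_A = runif(1, 0, 200), K_B = runif(1, 0, 200),
                    q_max = runif(1, 0, 2.5),
                    U_AA = runif(1, -30, 30), U_AB = runif(1, -30, 30),
                    U_BB = runif(1, -30, 30))
}
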