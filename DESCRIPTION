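Package: cdisorb
Title: Electrosorption of Weak Polyprotic Acids in Capacitive Deionization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward prediction and analysis toolkit for the capacitive
    deionization (CDI) of weak polyprotic organic acids such as maleic acid.
    Implements pH-dependent diprotic speciation with Davies activity
    corrections and an electrolyte conductivity model with inversion from
    (conductivity, pH) to species concentrations; the two-species cooperative
    Moreau adsorption isotherm and the charge-weighted potential-free loading
    (PFL); a steady-state genetic algorithm for isotherm parameter estimation
    from sequential-spike batch experiments; the modified-Donnan chain linking
    PFL, specific capacitance and cell voltage to charge efficiency and salt
    adsorption capacity; constant-current corrections (ohmic and electrolyte
    voltage drops, Tafel parasitic currents, coion-expulsion lag time,
    micropore pH shift) and an energy-cost estimator; and cycle-wise analysis
    of CDI effluent conductivity/pH time series including a forward trace
    synthesizer for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    minpack.lm
Config/testthat/edition: 3
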