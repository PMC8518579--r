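---
title: "Predicting electrosorption of weak organic acids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electrosorption of weak organic acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdisorb)
```

This vignette documents the scientific content of `cdisorb`: the models it
implements, the assumptions behind them, the parameters that matter, and
the design decisions taken where the underlying theory leaves choices
open. The running example is maleic acid (pKa 1.92/6.23) on the
activated-carbon electrode pair of a commercial flow-by CDI cell
(45 F/g, 2 x 1.66 g, 0.62 cm^3/g micropore volume).

## 1. Speciation and conductivity

A diprotic acid is speciated in closed form from pH: with `h = 10^-pH`
the fractions of H2A, HA- and A2- are `h^2 / D`, `Ka1 h / D` and
`Ka1 Ka2 / D` with `D = h^2 + Ka1 h + Ka1 Ka2`. Sodium (the pH is assumed
adjusted with NaOH only) follows from electroneutrality, H+ and OH- from
the pH and the water ion product. Temperature is fixed at 298.15 K
throughout; the equilibrium constants carry no temperature dependence.

Two modes are exposed everywhere:

* `ideal` - concentration-based constants, one-pass solution;
* `activity_corrected` - Davies activity coefficients
  (`log10 gamma = -0.509 z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)`) shift the
  apparent pKa values, and the system is closed by a fixed-point
  iteration over the ionic strength. The update is half-step damped
  (`I <- (I_old + I_new)/2`) because the undamped gamma-I loop can
  oscillate in its last digits; convergence is `|dI| < 1e-10` mol/L with
  a cap of 100 iterations.

Conductivity is the sum of limiting molar conductivities times
concentrations (`kappa [S/m] = sum(lambda_i c_i) / 10` with lambda in
S cm^2/mol and c in mol/L). In corrected mode each species' conductivity
is scaled by the Davies coefficient of its charge,
`lambda_i = lambda0_i gamma(z_i)`. This single-factor scaling is a
pragmatic model choice: it captures the leading ionic-strength dependence
with the same correlation used for the equilibria, and it is exposed as a
mode so the ideal variant remains available. The limiting molar
conductivities of the maleate species are not tabulated as precisely as
the inorganic ions; the defaults (41 S cm^2/mol for hydrogen maleate,
120 S cm^2/mol for maleate) are estimates by analogy with hydrogen
oxalate (40.2) and fumarate (~124) and are configurable.

The inverse problem - recovering the total acid concentration from a
measured (conductivity, pH) pair - is solved by a bracketed root search
(`uniroot`, bracket 0 to 2 mol/L, tolerance 1e-13): at fixed pH the
forward conductivity is strictly increasing in the total concentration,
so the root is unique. Samples whose conductivity lies below the ionic
floor set by H+/OH-/Na+ at that pH are flagged rather than fatal in trace
analysis.

## 2. The cooperative Moreau isotherm

Only the charged species adsorb: the neutral acid is practically absent
above pH 4 and is excluded from the adsorption and charge bookkeeping.
The two-species Moreau isotherm with interaction energies `U_AA`, `U_AB`,
`U_BB` (kJ/mol; positive = repulsive) is implemented exactly in its
stated form, including the coefficient asymmetry between numerator
(`2 c^2 K^2 e`) and denominator (`c^2 K^2 e`). Two consequences are worth
noting:

* a single species saturates at `2 q_max`, not `q_max` - the algebraic
  limit of the expression as written;
* with all interactions at zero and one species present, it reduces
  exactly to a Langmuir form `q = q_max 2Kc/(1+Kc)`, which the test suite
  uses as an anchor.

The Boltzmann factors are evaluated as `exp(-U/(RT))` with
RT = 2.479 kJ/mol at 298.15 K: the interaction parameters are tabulated
in kJ/mol, so the molar gas constant (not the single-molecule Boltzmann
constant) is the consistent scale.

The potential-free loading `PFL = |z_A| q_A + |z_B| q_B` uses charge
magnitudes, making it a positive equivalent loading (meq/g) - the form
in which it enters the charge-efficiency expression.

## 3. Charge efficiency and the mass-basis convention

The modified Donnan model links micropore and bulk concentrations through
a single dimensionless potential, `c_mi = c_ma exp(-z phi_D + mu_att)`.
For a symmetric cell the charge efficiency is `Lambda = tanh(phi_D/2)`,
and eliminating `phi_D` against the stored charge gives the closed form

`Lambda = tanh(0.5 arcsinh(Sigma / PFL_e))`, `Sigma = Cg dphi_cell/(4F)`.

**Mass basis.** Batch experiments measure PFL per gram of electrode
*pair*, but the coion reservoir that opposes charging of one electrode is
that electrode's share of the loading. The package therefore evaluates
the expression with `PFL_e = PFL/2` by default (`basis = "pair"`), with
an `"electrode"` switch for loadings already given per single electrode.
This convention is not a free parameter: it is fixed by requiring that
the same convention reproduces, simultaneously, the equilibrium
efficiencies at pH 4 and pH 8, the maximum Donnan potential of the
constant-current reference run, and the coion-expulsion lag time. The
halved basis is the only one that does; the package freezes it and the
acceptance tests pin it.

`mu_att`, the constant chemical-attraction term, is retained for
micropore bookkeeping and pedagogy but plays no role in the efficiency
predictions - there the saturating Moreau PFL takes its place, which is
precisely what keeps high feed concentrations from producing unphysical
loadings.

## 4. Constant-current corrections

* **Voltage drops** (applied threshold minus what charges the double
  layer): `dphi_eff = dphi_pot - R_setup I - (k_cell/kappa) I^2`. The
  electrolyte term is quadratic in the current; the cell constant's units
  (A m)^-1 force this reading. The feed-state conductivity is used and
  held constant over the step - depletion during the step lowers kappa
  and would increase the drop, so predictions err on the optimistic side;
  a user-supplied kappa can override.
* **Parasitic currents**: a Tafel law
  `I_redox = a exp((dphi_cell - dphi_crit)/b)` above a critical cell
  voltage (default 1.0 V), zero below. Its charge is integrated
  (trapezoidal rule, >= 200 steps) along the linear charging ramp from 0
  until the cell voltage - ohmic drops plus capacitive part - reaches the
  threshold, and `Lambda_corr = Lambda (1 - Q_redox/Sigma)`. The default
  Tafel parameters (a = 1 mA, b = 0.12 V) are placeholders standing in
  for a cell-specific calibration measurement; `calibrate_tafel()`
  rescales `a` to a measured parasitic charge fraction, exploiting that
  the integral is proportional to `a`. With the threshold fixed, the
  same parameters predict a *smaller* parasitic fraction at higher
  current (the window above the critical voltage is traversed faster) -
  the package asserts this ordering rather than absolute fractions.
* **Quasi-static limit**: as I -> 0 the drops vanish and the prediction
  reduces to the constant-voltage equilibrium value. Note that this
  continuity holds for the voltage/charge/efficiency chain only: with a
  nonzero Tafel pre-factor the parasitic fraction *diverges* as the ramp
  slows down, which is physically correct (an infinitely slow ramp burns
  all charge above the critical voltage). The consistency test therefore
  disables the Tafel term.
* **Lag time**: `t_E = PFL_e m_pair F / I`, the time to supply the charge
  that expels the pre-loaded coions; with the pair-basis convention this
  equals PFL times the single-electrode mass times F over I.

## 5. Isotherm fitting: the genetic algorithm

The fitter is an elitist steady-state GA exactly as specified for the
reference fit: population 10, the single best set kept unchanged, nine
children recombined from the best five, each gene mutated with
probability 0.2 by a uniform redraw from its full bound range
(K in [0, 1e5] L/mol, q_max in [0, 2.5] mmol/g, U in [-30, 30] kJ/mol),
fitness = R² of predicted vs observed total loadings.

The recombination operator is where the description leaves a choice, and
it matters. A gene-wise *discrete* pick from two parents cannot create
new coordinate values, so parameter resolution is limited to what
mutation happens to draw - on a [0, 1e5] range that is far too coarse to
resolve an affinity constant of order 20 L/mol within an accessible
budget. The package therefore uses *fitness-oriented intermediate
recombination*: the first parent is drawn rank-weighted from the top
five, the second is any other of the five, and each child gene is
`u x_better + (1-u) x_worse` with `u ~ U(0, 1.75)`, clipped to bounds.
The extrapolation beyond the better parent (u > 1) is essential: K_A and
q_max are strongly negatively correlated along a curved ridge of nearly
constant R², and a contracting blend stalls on that ridge within the
default budget. The u-range was chosen by benchmarking restart means
against an independent Levenberg-Marquardt fit of the same objective on
synthetic datasets; difference-vector (DE-style) moves were tried and
rejected for premature collapse with this small population.

Restarts are driven by one master seed that spawns per-restart seeds, so
a fit is bit-identical under a fixed seed while restarts remain
independent. Results report the per-restart table plus mean and SD over
all restarts - the convention in which such fits are usually tabulated -
and the best restart as `best_params`. The default budget (20,000
iterations x 10 restarts, a couple of minutes on one CPU) is the
package's scaled working budget; the full reference budget (200,000 x
100) is available through `ga_config()`.

**Weak identifiability is real and documented.** At 2% multiplicative
noise on a 36-point design, the interaction energies are only loosely
determined (U_AB in particular is unidentifiable once its Boltzmann
factor underflows toward zero - any strongly repulsive value fits
equally well), and even the maximum-likelihood estimates of K_A and
q_max scatter by several percent between noise realizations. The
parameter-recovery tests therefore target K_A and q_max at a 10%
tolerance and do not constrain the U parameters.

## 6. The synthetic-data generators

Two generators make the package self-testing; both are first-class,
seeded, tested code.

**Batch loadings** (`generate_synthetic_batch()`): total loadings from
the forward isotherm on a full-factorial (pH, concentration) design with
multiplicative Gaussian noise (default CV 2%, a choice - the noise level
of carbon-analysis-derived loadings is not otherwise constrained). The
default design spans the experimentally probed window (pH 4-9.5,
concentrations up to 60 mM) with points weighted toward low pH and high
concentration - pH {4, 4.5, 5, 5.5, 7, 9.5} x {5, 15, 25, 35, 50, 60} mM.
The weighting is deliberate design-for-identifiability: the loading
signal, and with it the Fisher information on K_A and q_max, is
concentrated below the second pKa and near saturation; a Monte-Carlo
study of the ML estimator showed evenly spaced grids inflate the
estimator's SD by roughly half again.

**Effluent traces** (`synthesize_trace()`): a cyclic steady-state trace
built from a performance prediction - feed concentration held for the
lag time `t_E`, an exponential-approach depletion sized so the
integrated SAC matches the prediction, and an exponential desorption
release returning exactly the adsorbed amount. Two balances are enforced
exactly: mass (integrated depletion = SAC x pair mass) and charge
(integrated current = Sigma x pair mass x F). When the nominal charging
ramp is too short for the flow to carry the predicted capacity at a
bounded depletion depth (default 60% of feed), the adsorption window is
stretched and the plateau current scaled down to preserve the charge
balance. The pH is held at the feed value and the conductivity follows
the forward speciation model, so the trace is exactly invertible at zero
noise.

What the generators do *not* emulate - and hence what passing tests do
not show about real data: residence-time dispersion and sensor dynamics,
the pH excursions of real ad/desorption cycles (held constant here),
electrode aging, CO2/carbonate chemistry (assumed degassed), and any
transport limitation inside the cell. Closure tests validate the
analysis chain's bookkeeping, not the cell physics.

## 7. Effluent analysis conventions

Cycles are detected from the applied-current program (current on =
adsorption); start-up cycles before cyclic steady state are dropped
(default 2) and the following cycles averaged (default: all remaining,
or `n_average`). SAC integrates the depletion by the trapezoidal rule on
the trace's own sampling grid (no resampling). The mean charge per
adsorbed molecule uses `z = alpha + 2(1 - alpha)` with `alpha` the
*flow-weighted* mean monovalent fraction over the adsorption window - an
averaging convention the package fixes explicitly since smooth traces
make window-mean and per-sample formulations agree closely.

## 8. Energy cost

The operating-cost estimator charges `rate z F / Lambda` coulombs per
hour at the capacitor-average voltage `dphi_max / 2` (energy =
0.5 Q dphi_max, the mean charging voltage of an ideal capacitor ramp) and
prices the energy at a tariff (default 0.1 EUR/kWh). It is an
order-of-magnitude figure by construction: no capital, replacement,
pumping or inverter losses. The half-voltage assumption is recorded in
the function's output.

## 9. Numerical choices, degenerate inputs, limits

* Fixed-point tolerance 1e-10 mol/L on ionic strength, damped update,
  100-iteration cap (error on non-convergence).
* `uniroot` brackets [0, 2 mol/L] for the conductivity inversion;
  conductivities below the ionic floor raise identifiable errors.
* Trapezoidal integration everywhere (Tafel charge >= 200 steps; traces
  on their native grid).
* Zero PFL makes the charge efficiency 1 by its limit - reported with a
  warning rather than an error.
* The Tafel current at exactly the critical voltage equals the
  pre-factor `a` (the clamp applies strictly below).
* Problem sizes in the tests and the acceptance script - 36-point
  designs, 20,000-iteration GA runs, a handful of synthesized cycles -
  are the package's scaled working sizes, chosen to keep a full
  verification run in the minutes range on a single CPU.

## 10. Known limitations

The framework is deliberately quasi-static: it predicts end-of-step
capacities and efficiencies, not the temporal evolution of the effluent.
The specific capacitance is treated as voltage- and
electrolyte-independent; the double layer is a single-potential modified
Donnan picture, not Gouy-Chapman-Stern; ion pairing and Pitzer-level
activity models are out of scope; micropore dissociation equilibria are
not imposed (the bulk constants cannot hold there, and only bounds on
the micropore pH shift are derived). Tafel parameters and the exact
conductivity-activity correction are cell- and chemistry-specific inputs
that a user should calibrate for quantitative work on other systems.
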