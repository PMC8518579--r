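#' Define a diprotic weak acid
#'
#' Bundles the dissociation constants, molar mass, species charges and
#' limiting molar conductivities needed by the speciation, conductivity and
#' isotherm routines. The three acid species are the fully protonated acid
#' H2A (neutral), the monovalent anion HA- and the divalent anion A2-.
#'
#' Limiting molar conductivities are given per ionic species in
#' S cm^2/mol. Values for Na+, H+ and OH- come from standard tables; the
#' defaults for the acid anions are estimates for maleate by analogy with
#' structurally similar dicarboxylates (hydrogen oxalate ~40, fumarate ~124)
#' and can be overridden.
#'
#' @param name Short label for the acid.
#' @param pKa1,pKa2 First and second dissociation exponents; `pKa1 < pKa2`.
#' @param molar_mass Molar mass in g/mol.
#' @param lambda0 Named numeric vector of limiting molar conductivities in
#'   S cm^2/mol with entries `Na`, `H`, `OH`, `HA`, `A2`.
#' @return An object of class `acid_definition`.
#' @examples
#' maleic_acid()
#' @export
acid_definition <- function(name, pKa1, pKa2, molar_mass,
                            lambda0 = c(Na = 50.11, H = 349.8, OH = 198.0,
                                        HA = 41, A2 = 120)) {
  stopifnot(is.numeric(pKa1), is.numeric(pKa2), length(pKa1) == 1L,
            length(pKa2) == 1L, pKa1 < pKa2,
            is.numeric(molar_mass), molar_mass > 0)
  need <- c("Na", "H", "OH", "HA", "A2")
  if (!all(need %in% names(lambda0)))
    stop("lambda0 must name conductivities for: ", paste(need, collapse = ", "))
  lambda0 <- lambda0[need]
  if (any(lambda0 <= 0)) stop("limiting molar conductivities must be > 0")
  structure(list(name = as.character(name),
                 pKa1 = pKa1, pKa2 = pKa2,
                 Ka1 = 10^(-pKa1), Ka2 = 10^(-pKa2),
                 molar_mass = molar_mass,
                 species_charges = c(H2A = 0L, HA = -1L, A2 = -2L),
                 lambda0 = lambda0),
            class = "acid_definition")
}

#' Maleic acid definition
#'
#' Maleic acid (cis-butenedioic acid), pKa 1.92 and 6.23, 116.07 g/mol,
#' the model weak diprotic acid of this package.
#'
#' @param ... Overrides passed on to [acid_definition()] (e.g. `lambda0`).
#' @return An `acid_definition`.
#' @export
maleic_acid <- function(...) {
  args <- modifyList(list(name = "maleic acid", pKa1 = 1.92, pKa2 = 6.23,
                          molar_mass = 116.07), list(...))
  do.call(acid_definition, args)
}

#' @export
print.acid_definition <- function(x, ...) {
  cat(sprintf("<acid_definition> %s: pKa %.2f / %.2f, M %.2f g/mol\n",
              x$name, x$pKa1, x$pKa2, x$molar_mass))
  invisible(x)
}

#' Davies activity coefficient (log10)
#'
#' Empirical Debye-Hueckel extension valid up to moderate ionic strength:
#' `log10(gamma) = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - 0.3 * I)` with
#' A = 0.509 at 25 degC.
#'
#' @param charge Integer ion charge (sign is irrelevant, enters as z^2).
#' @param ionic_strength Ionic strength in mol/L, >= 0. Vectorized.
#' @return log10 of the activity coefficient.
#' @examples
#' davies_log_gamma(1, 0.05)   # -0.0854
#' @export
davies_log_gamma <- function(charge, ionic_strength) {
  stopifnot(all(ionic_strength >= 0))
  s <- sqrt(ionic_strength)
  -.DAVIES_A * charge^2 * (s / (1 + s) - 0.3 * ionic_strength)
}

# Shifted (concentration-based) pKa values under Davies corrections.
# pH is an activity scale, so gamma terms move the apparent constants:
#   pKa1' = pKa1 + log10(gamma_1), pKa2' = pKa2 + log10(gamma_2/gamma_1).
.effective_pkas <- function(acid, ionic_strength) {
  lg1 <- davies_log_gamma(1, ionic_strength)
  lg2 <- davies_log_gamma(2, ionic_strength)
  list(pKa1 = acid$pKa1 + lg1, pKa2 = acid$pKa2 + (lg2 - lg1))
}

#' Equilibrium fractions of the acid species at a given pH
#'
#' Closed-form diprotic speciation: with `h = 10^-pH`,
#' denominators `h^2 + Ka1*h + Ka1*Ka2` give the fractions of H2A, HA- and
#' A2- summing to one. In `activity_corrected` mode the concentration-based
#' constants are shifted by Davies log-gamma terms at the supplied ionic
#' strength.
#'
#' @param pH Solution pH (activity scale), vectorized.
#' @param acid An [acid_definition()].
#' @param mode `"ideal"` or `"activity_corrected"`.
#' @param ionic_strength Ionic strength in mol/L; required in
#'   `activity_corrected` mode.
#' @return A matrix with one row per pH and columns `H2A`, `HA`, `A2`.
#' @examples
#' species_fractions(8, maleic_acid())   # A2- fraction 0.9833
#' @export
species_fractions <- function(pH, acid,
                              mode = c("ideal", "activity_corrected"),
                              ionic_strength = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(pH >= 0 & pH <= 14))
  if (mode == "activity_corrected") {
    if (is.null(ionic_strength))
      stop("ionic_strength is required in activity_corrected mode")
    pk <- .effective_pkas(acid, ionic_strength)
    Ka1 <- 10^(-pk$pKa1); Ka2 <- 10^(-pk$pKa2)
  } else {
    Ka1 <- acid$Ka1; Ka2 <- acid$Ka2
  }
  h <- 10^(-pH)
  denom <- h^2 + Ka1 * h + Ka1 * Ka2
  cbind(H2A = h^2 / denom, HA = Ka1 * h / denom, A2 = Ka1 * Ka2 / denom)
}
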