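#' Sequential-spike batch adsorption series
#'
#' Describes the batch experiment used to measure potential-free loadings:
#' a recirculating volume is equilibrated with the electrodes, a sample of
#' `replaced_volume` is withdrawn and replaced by concentrated stock, and
#' the cycle repeats, stepping the equilibrium concentration upwards.
#'
#' @param initial_concentration Acid concentration before the first
#'   equilibration, mol/L.
#' @param records data.frame with columns `cycle` (1, 2, ...), `pH_eq` and
#'   `c_eq` (equilibrium concentration, mol/L), one row per cycle.
#' @param initial_volume Total liquid volume V in L.
#' @param replaced_volume Volume exchanged against stock per spike, L.
#' @param stock_concentration Stock (spike) concentration, mol/L.
#' @param electrode_mass Total sorbent (electrode pair) mass in g.
#' @return An object of class `batch_series`.
#' @export
batch_series <- function(initial_concentration, records,
                         initial_volume = 0.05, replaced_volume = 0.004,
                         stock_concentration = 0.2, electrode_mass = 3.32) {
  stopifnot(replaced_volume <= initial_volume, initial_volume > 0,
            electrode_mass > 0, initial_concentration >= 0)
  records <- as.data.frame(records)
  if (!all(c("cycle", "c_eq") %in% names(records)))
    stop("records needs columns 'cycle' and 'c_eq'")
  if (!identical(as.integer(records$cycle), seq_len(nrow(records))))
    stop("cycle indices must be consecutive from 1")
  if (any(records$c_eq < 0)) stop("c_eq must be non-negative")
  structure(list(initial_concentration = initial_concentration,
                 initial_volume = initial_volume,
                 replaced_volume = replaced_volume,
                 stock_concentration = stock_concentration,
                 electrode_mass = electrode_mass,
                 records = records),
            class = "batch_series")
}

#' Concentration after a stock spike
#'
#' Mixing rule for replacing `replaced_volume` of solution at `c_prev` with
#' stock: `c = (c_prev * (V - Vr) + c_stock * Vr) / V`.
#'
#' @param c_prev Concentration before the spike, mol/L.
#' @param series A [batch_series()].
#' @return Concentration after the spike, mol/L.
#' @examples
#' s <- batch_series(0.005, data.frame(cycle = 1, pH_eq = 7, c_eq = 0.004))
#' spike_concentration(0.005, s) * 1000   # 20.6 mM
#' @export
spike_concentration <- function(c_prev, series) {
  stopifnot(all(c_prev >= 0))
  V <- series$initial_volume
  Vr <- series$replaced_volume
  (c_prev * (V - Vr) + series$stock_concentration * Vr) / V
}

#' Cumulative loadings from a sequential-spike series
#'
#' Reconstructs the cumulative loading per cycle:
#' `q_1 = (c_0 - c*_1) V / m`, and for later cycles
#' `q_y = q_{y-1} + (c_y - c*_y) V / m` where `c_y` is the post-spike start
#' concentration computed with [spike_concentration()] from the previous
#' equilibrium. Negative increments (desorption upon dilution) are allowed.
#'
#' @param series A [batch_series()].
#' @return A data.frame with one row per cycle: `cycle`, `pH_eq`,
#'   `c_start` and `c_eq` (mol/L) and the cumulative loading `q_mmol_g`.
#' @export
loading_sequence <- function(series) {
  rec <- series$records
  V <- series$initial_volume
  m <- series$electrode_mass
  n <- nrow(rec)
  c_start <- numeric(n)
  q <- numeric(n)
  c_start[1] <- series$initial_concentration
  q[1] <- (c_start[1] - rec$c_eq[1]) * V / m * 1000
  if (n > 1) for (y in 2:n) {
    c_start[y] <- spike_concentration(rec$c_eq[y - 1], series)
    q[y] <- q[y - 1] + (c_start[y] - rec$c_eq[y]) * V / m * 1000
  }
  data.frame(cycle = rec$cycle,
             pH_eq = if ("pH_eq" %in% names(rec)) rec$pH_eq else NA_real_,
             c_start = c_start, c_eq = rec$c_eq, q_mmol_g = q)
}

#' Generate a synthetic equilibrium-loading dataset
#'
#' Forward-simulates total loadings on a (pH, concentration) design from
#' the Moreau model with ideal speciation, optionally perturbed by
#' multiplicative Gaussian noise, for fitter validation and parameter
#' recovery studies.
#'
#' The default design covers the experimentally probed window (pH 4-9.5,
#' 1-60 mM) with points weighted towards low pH and high concentration,
#' where the loading signal - and hence the information on `K_A` and
#' `q_max` - is concentrated.
#'
#' @param true_params A [moreau_parameters()] object generating the data.
#' @param acid An [acid_definition()].
#' @param pH,c_eq_mM Vectors defining the full-factorial design.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `pH`, `c_eq_mM`, `q_mmol_g`.
#' @export
generate_synthetic_batch <- function(true_params, acid,
                                     pH = c(4, 4.5, 5, 5.5, 7, 9.5),
                                     c_eq_mM = c(5, 15, 25, 35, 50, 60),
                                     noise_cv = 0.02, seed = NULL) {
  stopifnot(noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- pfl_grid(pH, c_eq_mM, true_params, acid)
  q <- g$q_total
  if (noise_cv > 0) q <- q * (1 + rnorm(length(q), 0, noise_cv))
  data.frame(pH = g$pH, c_eq_mM = g$c_total_mM, q_mmol_g = q)
}

#' Read / write equilibrium-loading datasets
#'
#' Delimited text (tab-separated) with header columns `pH`, `c_eq_mM`,
#' `q_mmol_g`.
#'
#' @param path File path.
#' @param dataset A data.frame as from [generate_synthetic_batch()].
#' @return `read_batch_dataset` returns the data.frame;
#'   `write_batch_dataset` returns `path` invisibly.
#' @export
read_batch_dataset <- function(path) {
  d <- read.delim(path)
  need <- c("pH", "c_eq_mM", "q_mmol_g")
  if (!all(need %in% names(d)))
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_batch_dataset
#' @export
write_batch_dataset <- function(dataset, path) {
  write.table(dataset, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
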