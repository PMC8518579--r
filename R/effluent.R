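#' Effluent time series of a CDI experiment
#'
#' A data.frame of on-line sensor readings behind the cell, with the feed
#' composition attached as attributes. Columns: `time_s` (strictly
#' increasing), `conductivity_S_m`, `pH`, `flow_L_min`, `current_A` (the
#' applied current program; 0 during desorption).
#'
#' @param time_s,conductivity_S_m,pH,flow_L_min,current_A Per-sample
#'   vectors of equal length.
#' @param feed_c_total Feed total acid concentration in mol/L.
#' @param feed_pH Feed pH.
#' @return A data.frame of class `effluent_trace`.
#' @export
effluent_trace <- function(time_s, conductivity_S_m, pH, flow_L_min,
                           current_A, feed_c_total, feed_pH) {
  stopifnot(all(diff(time_s) > 0), all(conductivity_S_m >= 0),
            all(flow_L_min >= 0), all(current_A >= 0))
  n <- length(time_s)
  stopifnot(length(conductivity_S_m) == n, length(pH) == n,
            length(flow_L_min) == n, length(current_A) == n)
  structure(data.frame(time_s = time_s,
                       conductivity_S_m = conductivity_S_m, pH = pH,
                       flow_L_min = flow_L_min, current_A = current_A),
            feed_c_total = feed_c_total, feed_pH = feed_pH,
            class = c("effluent_trace", "data.frame"))
}

#' Read / write effluent traces
#'
#' Tab-separated text with header `time_s`, `conductivity_S_m`, `pH`,
#' `flow_L_min`, `current_A`; the feed composition is carried in two
#' comment lines `# feed_c_total` and `# feed_pH` at the top.
#'
#' @param path File path.
#' @param trace An [effluent_trace()].
#' @export
read_effluent_trace <- function(path) {
  hdr <- readLines(path, n = 2L)
  getval <- function(key) {
    ln <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (!length(ln)) stop("missing '# ", key, "' header line")
    as.numeric(sub(".*=", "", ln))
  }
  d <- read.delim(path, comment.char = "#")
  effluent_trace(d$time_s, d$conductivity_S_m, d$pH, d$flow_L_min,
                 d$current_A, getval("feed_c_total"), getval("feed_pH"))
}

#' @rdname read_effluent_trace
#' @export
write_effluent_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# feed_c_total = %.10g", attr(trace, "feed_c_total")),
               sprintf("# feed_pH = %.10g", attr(trace, "feed_pH"))), con)
  write.table(as.data.frame(trace), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Per-sample total acid concentration from an effluent trace
#'
#' Applies [invert_conductivity()] to every (conductivity, pH) sample.
#' Samples where the inversion fails (conductivity below the ionic floor
#' for the recorded pH) are flagged and returned as `NA` rather than
#' aborting the analysis.
#'
#' @param trace An [effluent_trace()].
#' @param acid An [acid_definition()].
#' @param mode Speciation/conductivity mode.
#' @return A data.frame with `c_total` (mol/L) and logical `converged`.
#' @export
trace_to_concentrations <- function(trace, acid, mode = "ideal") {
  n <- nrow(trace)
  ct <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(invert_conductivity(trace$conductivity_S_m[i],
                                        trace$pH[i], acid, mode),
                    error = function(e) NULL)
    if (!is.null(res)) {
      ct[i] <- res$c_total
      ok[i] <- TRUE
    }
  }
  data.frame(c_total = ct, converged = ok)
}

#' Integrated salt adsorption capacity over a window
#'
#' `SAC = integral(Vdot * (c0 - c_out) dt) / m` by the trapezoidal rule
#' over the selected sample window, in mol per gram of electrode pair.
#'
#' @param c_series Per-sample total concentration in mol/L (e.g. from
#'   [trace_to_concentrations()]).
#' @param trace The corresponding [effluent_trace()].
#' @param electrode_pair_mass Mass of both electrodes in g.
#' @param window Integer indices of the samples to integrate over.
#' @return SAC in mol/g (positive = net adsorption).
#' @export
integrate_sac <- function(c_series, trace, electrode_pair_mass, window) {
  if (!length(window)) stop("empty integration window")
  tt <- trace$time_s[window]
  flow_L_s <- trace$flow_L_min[window] / 60
  c0 <- attr(trace, "feed_c_total")
  integrand <- flow_L_s * (c0 - c_series[window])
  pracma::trapz(tt, integrand) / electrode_pair_mass
}

#' Experimental charge efficiency from SAC and supplied charge
#'
#' `Lambda = F * SAC * (1 * alpha + 2 * (1 - alpha)) * m / charge * 100%`:
#' adsorbed equivalents (SAC times the mean charge of the adsorbing
#' species) over the electrical charge supplied.
#'
#' @param sac_mol SAC in mol per gram of electrode pair.
#' @param alpha Mean monovalent fraction of the adsorbing species.
#' @param charge Supplied charge in C, > 0.
#' @param electrode_pair_mass Mass of both electrodes in g.
#' @return Charge efficiency in percent.
#' @export
charge_efficiency_exp <- function(sac_mol, alpha, charge,
                                  electrode_pair_mass) {
  stopifnot(charge > 0)
  z_mean <- alpha + 2 * (1 - alpha)
  .FARADAY * sac_mol * z_mean * electrode_pair_mass / charge * 100
}

#' Detect adsorption/desorption cycles from the current program
#'
#' Splits the trace at the edges of the applied-current program: samples
#' with `current_A > 0` form adsorption windows, the following zero-current
#' stretches desorption windows.
#'
#' @param trace An [effluent_trace()].
#' @return A data.frame with one row per cycle: `cycle`, `ads_start`,
#'   `ads_end`, `des_start`, `des_end` (sample indices; the desorption
#'   columns are `NA` for a trailing unfinished cycle).
#' @export
detect_cycles <- function(trace) {
  on <- trace$current_A > 0
  if (!any(on)) stop("no adsorption phases: current program is all zero")
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ads <- which(r$values)
  out <- data.frame(cycle = seq_along(ads),
                    ads_start = starts[ads], ads_end = ends[ads],
                    des_start = NA_integer_, des_end = NA_integer_)
  for (i in seq_along(ads)) {
    j <- ads[i] + 1L
    if (j <= length(r$values) && !r$values[j]) {
      out$des_start[i] <- starts[j]
      out$des_end[i] <- ends[j]
    }
  }
  out
}

#' Cycle-wise SAC and charge efficiency of an effluent trace
#'
#' Inverts the trace to concentrations, detects cycles, and computes per
#' adsorption window the SAC (Eq.-8-style integral), the supplied charge,
#' the flow-weighted mean monovalent fraction alpha, and the experimental
#' charge efficiency. The summary row averages the retained cycles
#' (dropping start-up cycles before cyclic steady state).
#'
#' @param trace An [effluent_trace()].
#' @param acid An [acid_definition()].
#' @param electrode_pair_mass Mass of both electrodes in g.
#' @param drop_cycles Number of initial cycles to discard.
#' @param n_average Number of cycles to average after the dropped ones
#'   (`NULL` = all remaining).
#' @param mode Speciation mode for the inversion.
#' @return A list with `per_cycle` (data.frame) and `summary` (one-row
#'   data.frame of means over the retained cycles).
#' @export
analyze_cycles <- function(trace, acid, electrode_pair_mass = 3.32,
                           drop_cycles = 2L, n_average = NULL,
                           mode = "ideal") {
  conc <- trace_to_concentrations(trace, acid, mode)
  cyc <- detect_cycles(trace)
  fr <- species_fractions(trace$pH, acid)
  alpha_all <- fr[, "HA"] / (fr[, "HA"] + fr[, "A2"])

  rows <- lapply(seq_len(nrow(cyc)), function(i) {
    w <- cyc$ads_start[i]:cyc$ads_end[i]
    sac <- integrate_sac(conc$c_total, trace, electrode_pair_mass, w)
    charge <- pracma::trapz(trace$time_s[w], trace$current_A[w])
    wgt <- trace$flow_L_min[w]
    alpha <- sum(alpha_all[w] * wgt) / sum(wgt)
    z_mean <- alpha + 2 * (1 - alpha)
    data.frame(cycle = cyc$cycle[i], sac_mol_g = sac,
               sac_eq_g = sac * z_mean, charge_C = charge,
               alpha_mean = alpha,
               lambda_pct = charge_efficiency_exp(sac, alpha, charge,
                                                  electrode_pair_mass))
  })
  per_cycle <- do.call(rbind, rows)
  keep <- per_cycle$cycle > drop_cycles
  if (!is.null(n_average))
    keep <- keep & per_cycle$cycle <= drop_cycles + n_average
  if (!any(keep))
    stop("no cycles left after dropping ", drop_cycles)
  kept <- per_cycle[keep, -1]
  list(per_cycle = per_cycle,
       summary = as.data.frame(as.list(colMeans(kept))),
       cycles_used = per_cycle$cycle[keep])
}

#' Synthesize a cyclic effluent trace from a performance prediction
#'
#' Forward-generates a plausible cyclic steady-state trace for testing the
#' analysis chain: each adsorption phase holds the feed concentration for
#' the coion-expulsion lag `t_E`, then depletes along an exponential
#' approach whose amplitude is sized so the integrated SAC matches
#' `prediction$sac_mol_g`; the desorption phase releases the same amount
#' (mass conservation in cyclic steady state). The pH is held at the feed
#' value and the conductivity follows the forward speciation model, so the
#' trace is exactly invertible at zero noise.
#'
#' Two balances are enforced exactly: the effluent mass balance
#' (integrated depletion = predicted SAC times the pair mass) and the
#' charge balance (integrated current = predicted specific charge times
#' pair mass and Faraday constant). When the nominal charging ramp is too
#' short for the flow to carry the predicted capacity at a bounded
#' depletion depth (`max_depletion` of the feed), the adsorption window is
#' stretched and the plateau current scaled down accordingly - a synthetic
#' idealization, not a transport model.
#'
#' @param op An [operating_point()] (constant-current).
#' @param prediction A one-row prediction from
#'   [predict_constant_current()].
#' @param acid An [acid_definition()].
#' @param spec A [cell_spec()].
#' @param n_cycles Number of adsorption/desorption cycles.
#' @param dt_s Sampling interval in s.
#' @param desorb_s Desorption phase duration in s.
#' @param noise Relative standard deviation of multiplicative sensor noise
#'   on the conductivity.
#' @param seed Optional seed.
#' @param mode Speciation mode used for the forward conductivity.
#' @param max_depletion Maximum depletion depth as a fraction of the feed
#'   concentration.
#' @return An [effluent_trace()].
#' @export
synthesize_trace <- function(op, prediction, acid, spec, n_cycles = 6L,
                             dt_s = 10, desorb_s = 2400, noise = 0,
                             seed = NULL, mode = "ideal",
                             max_depletion = 0.6) {
  stopifnot(op$current > 0, n_cycles >= 1, op$flow_rate > 0,
            max_depletion > 0, max_depletion < 1)
  if (!is.null(seed)) set.seed(seed)
  m <- pair_mass(spec)
  flow_L_s <- op$flow_rate / 60
  moles <- prediction$sac_mol_g * m       # mol adsorbed per cycle
  charge_C <- prediction$sigma_eq_g * m * .FARADAY

  t_ramp <- spec$Cg * prediction$dphi_eff_V * m / (4 * op$current)
  t_E <- prediction$t_E_s
  # shortest depletion window that fits the moles at the depth cap
  # (the factor 0.683 is the mean of the tau = T/3 exponential approach)
  t_depl <- moles / (flow_L_s * 0.683 * max_depletion * op$feed_c_total)
  t_ads <- max(t_ramp, t_E + t_depl)
  i_plateau <- charge_C / t_ads           # keeps the charge balance exact

  t_cycle <- seq(0, t_ads + desorb_s, by = dt_s)
  ads <- t_cycle <= t_ads
  # depletion shape: exponential approach after the lag
  tau <- (t_ads - t_E) / 3
  g <- ifelse(ads & t_cycle > t_E, 1 - exp(-(t_cycle - t_E) / tau), 0)
  denom <- pracma::trapz(t_cycle[ads], g[ads])
  A <- moles / (flow_L_s * denom)
  # desorption: exponential release conserving mass over the full cycle
  tau_d <- desorb_s / 5
  h <- ifelse(ads, 0, exp(-(t_cycle - t_ads) / tau_d))
  B <- moles / (flow_L_s * pracma::trapz(t_cycle[!ads], h[!ads]))
  c_out <- pmax(op$feed_c_total - A * g + B * h, 0)

  one_kappa <- vapply(c_out, function(ct)
    solve_solution_state(ct, op$feed_pH, acid, mode)$conductivity,
    numeric(1))
  nper <- length(t_cycle)
  time_s <- as.vector(vapply(seq_len(n_cycles) - 1L,
                             function(k) t_cycle + k * (t_ads + desorb_s + dt_s),
                             numeric(nper)))
  kappa <- rep(one_kappa, n_cycles)
  if (noise > 0) kappa <- kappa * (1 + rnorm(length(kappa), 0, noise))
  effluent_trace(time_s = time_s, conductivity_S_m = kappa,
                 pH = rep(op$feed_pH, length(kappa)),
                 flow_L_min = rep(op$flow_rate, length(kappa)),
                 current_A = rep(ifelse(ads, i_plateau, 0), n_cycles),
                 feed_c_total = op$feed_c_total, feed_pH = op$feed_pH)
}
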