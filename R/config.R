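#' Analysis configuration
#'
#' Bundles every tunable constant of the reconstruction pipeline. Defaults
#' reproduce the standard protocol for rhythmic-network recordings: the cycle
#' divided into 100 phase bins, a 0.1 s moving-median window for spike
#' removal, traces downsampled to 100 Hz, the reference nerve signal rectified
#' and integrated with a 0.05 s time constant, burst onsets at 10% of burst
#' amplitude, epochs accepted when the cycle-period coefficient of variation
#' is below 10% and at least three current steps were each held for at least
#' five cycles, a default excitatory reversal of -10 mV, sensitivity-scan
#' ranges of \[-20, 0\] mV (excitation) and \[-110, -90\] mV (inhibition), and
#' a 0.05 significance level.
#'
#' Canonical units are mV, pA and s throughout; conductances are reported in
#' nS and resistances in megaohm (the regression slope mV/pA is a gigaohm and
#' is converted once, centrally).
#'
#' @param n_bins number of phase bins per cycle.
#' @param median_window moving-median spike-removal window, s.
#' @param target_rate analysis sample rate after downsampling, Hz.
#' @param integrator_tau time constant of the reference-signal leaky
#'   integrator, s.
#' @param burst_threshold_frac burst-onset threshold as a fraction of burst
#'   amplitude above baseline.
#' @param cv_max maximal admissible coefficient of variation of the cycle
#'   period.
#' @param min_steps minimal number of held current (or voltage) steps.
#' @param min_cycles_per_step minimal number of cycles a step must be held.
#' @param step_tolerance plateau tolerance when identifying held levels
#'   (pA in current clamp, mV in voltage clamp).
#' @param transient_window time excluded after every step change, s.
#' @param v_window analysis window of membrane potentials, mV; only samples
#'   inside it enter the per-bin regressions (hyperpolarized operation keeps
#'   voltage-gated currents closed).
#' @param n_min minimal number of samples per valid phase bin.
#' @param drift_max maximal admissible baseline drift, mV/min.
#' @param e_e_default excitatory reversal potential used when the wedge
#'   diagram shows no identifiable zero-inhibition boundary, mV.
#' @param e_i_fallback inhibitory reversal potential used when wedge
#'   estimation fails, mV.
#' @param e_e_range,e_i_range reversal-potential ranges for the sensitivity
#'   scan, mV.
#' @param e_e_plausible acceptance window for a wedge-estimated excitatory
#'   reversal, mV.
#' @param boundary_min_bins minimal number of bins in a wedge boundary fit.
#' @param boundary_min_r2 minimal R-squared of a wedge boundary fit.
#' @param alpha significance level of the one-tailed z-test.
#' @param p_adjust multiple-testing correction: `"none"` (default) or `"BH"`.
#' @param rng_seed integer seed recorded in output headers for provenance.
#'
#' @return An object of class `"sc_config"` (a validated list).
#' @export
#' @examples
#' cfg <- sc_config()
#' cfg$n_bins
sc_config <- function(n_bins = 100L,
                      median_window = 0.1,
                      target_rate = 100,
                      integrator_tau = 0.05,
                      burst_threshold_frac = 0.10,
                      cv_max = 0.10,
                      min_steps = 3L,
                      min_cycles_per_step = 5L,
                      step_tolerance = 5,
                      transient_window = 0.05,
                      v_window = c(-100, -60),
                      n_min = 10L,
                      drift_max = 1,
                      e_e_default = -10,
                      e_i_fallback = -100,
                      e_e_range = c(-20, 0),
                      e_i_range = c(-110, -90),
                      e_e_plausible = c(-30, 10),
                      boundary_min_bins = 5L,
                      boundary_min_r2 = 0.9,
                      alpha = 0.05,
                      p_adjust = c("none", "BH"),
                      rng_seed = NA_integer_) {
  p_adjust <- match.arg(p_adjust)
  cfg <- list(
    n_bins = as.integer(n_bins), median_window = median_window,
    target_rate = target_rate, integrator_tau = integrator_tau,
    burst_threshold_frac = burst_threshold_frac, cv_max = cv_max,
    min_steps = as.integer(min_steps),
    min_cycles_per_step = as.integer(min_cycles_per_step),
    step_tolerance = step_tolerance, transient_window = transient_window,
    v_window = as.numeric(v_window), n_min = as.integer(n_min),
    drift_max = drift_max, e_e_default = e_e_default,
    e_i_fallback = e_i_fallback, e_e_range = as.numeric(e_e_range),
    e_i_range = as.numeric(e_i_range),
    e_e_plausible = as.numeric(e_e_plausible),
    boundary_min_bins = as.integer(boundary_min_bins),
    boundary_min_r2 = boundary_min_r2, alpha = alpha, p_adjust = p_adjust,
    rng_seed = as.integer(rng_seed)
  )
  validate_sc_config(cfg)
  structure(cfg, class = "sc_config")
}

validate_sc_config <- function(cfg) {
  stopifnot(
    cfg$n_bins >= 2L,
    cfg$median_window > 0,
    cfg$target_rate > 0,
    cfg$integrator_tau > 0,
    cfg$burst_threshold_frac > 0, cfg$burst_threshold_frac < 1,
    cfg$cv_max > 0,
    cfg$min_steps >= 1L,
    cfg$min_cycles_per_step >= 1L,
    cfg$step_tolerance > 0,
    cfg$transient_window >= 0,
    length(cfg$v_window) == 2L, cfg$v_window[1] < cfg$v_window[2],
    cfg$n_min >= 3L,
    length(cfg$e_e_range) == 2L, cfg$e_e_range[1] <= cfg$e_e_range[2],
    length(cfg$e_i_range) == 2L, cfg$e_i_range[1] <= cfg$e_i_range[2],
    cfg$boundary_min_bins >= 3L,
    cfg$boundary_min_r2 > 0, cfg$boundary_min_r2 <= 1,
    cfg$alpha > 0, cfg$alpha < 1
  )
  invisible(cfg)
}

#' Reversal potential pair
#'
#' @param e_i inhibitory reversal potential, mV.
#' @param e_e excitatory reversal potential, mV. Must exceed `e_i`: the
#'   decomposition denominator is `e_e - e_i`.
#' @return An object of class `"reversal_pair"`.
#' @export
#' @examples
#' reversal_pair(-90, -10)
reversal_pair <- function(e_i, e_e) {
  e_i <- as.numeric(e_i); e_e <- as.numeric(e_e)
  if (length(e_i) != 1L || length(e_e) != 1L || !is.finite(e_i) ||
      !is.finite(e_e)) {
    stop("reversal potentials must be single finite numbers", call. = FALSE)
  }
  if (e_e <= e_i) {
    stop("excitatory reversal must exceed inhibitory reversal (e_e > e_i)",
         call. = FALSE)
  }
  structure(list(e_i = e_i, e_e = e_e), class = "reversal_pair")
}

# stable short hash of the serialized configuration (polynomial rolling
# hash over the key=value list); provenance only, not cryptographic
config_hash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_header_lines <- function(cfg) {
  vals <- vapply(unclass(cfg), function(x)
    paste(format(x, digits = 15), collapse = ","), "")
  c(sprintf("# config_hash=%s", config_hash(cfg)),
    sprintf("# config.%s=%s", names(vals), vals))
}
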