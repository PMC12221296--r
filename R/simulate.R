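#' Single-compartment neuron parameters
#'
#' Parameters of the passive current-balance model
#' `C dVm/dt = g_leak (E_leak - Vm) + gi(t) (Ei - Vm) + ge(t) (Ee - Vm)
#' + I_inj(t)`. Defaults represent a rhythmic brainstem interneuron: a
#' leak-to-capacitance ratio of 100 pS/pF, i.e. a 10 ms membrane time
#' constant.
#'
#' @param C membrane capacitance, pF.
#' @param g_leak leak conductance, nS.
#' @param E_leak leak reversal potential, mV.
#' @param E_i,E_e inhibitory and excitatory synaptic reversal potentials,
#'   mV (`E_i < E_e`).
#' @param spike_threshold threshold of the optional threshold-reset spike
#'   generator, mV, or `NA` (default) to disable spiking. Spiking here only
#'   exists to exercise the median filter; the reconstruction itself
#'   assumes hyperpolarized, non-spiking operation.
#' @param spike_reset post-spike reset potential, mV.
#' @return An object of class `"neuron_params"`.
#' @export
neuron_params <- function(C = 100, g_leak = 10, E_leak = -65,
                          E_i = -90, E_e = -10,
                          spike_threshold = NA_real_, spike_reset = -65) {
  stopifnot(C > 0, g_leak > 0, E_i < E_e)
  structure(list(C = C, g_leak = g_leak, E_leak = E_leak, E_i = E_i,
                 E_e = E_e, spike_threshold = spike_threshold,
                 spike_reset = spike_reset),
            class = "neuron_params")
}

#' Membrane time constant
#'
#' `tau_m = C / g_leak`; with `C` in pF and `g_leak` in nS the result is in
#' ms. The quasi-static assumption underlying the reconstruction requires
#' this to be much shorter than the synaptic-drive time scale, and it sets
#' the method's time resolution as a fraction of the cycle period.
#'
#' @param params a [neuron_params()].
#' @return Time constant, ms.
#' @export
membrane_time_constant <- function(params = neuron_params()) {
  params$C / params$g_leak
}

#' Periodic synaptic conductance template
#'
#' A phase-locked conductance waveform: `baseline` outside the phase window
#' `[phi_on, phi_off)` and a shaped excursion from `baseline` to `peak`
#' inside it. `phi_off` may exceed 1 to wrap across the cycle boundary.
#' Shapes: `constant` (boxcar at `peak`), `ramp` (linear 0 to 1),
#' `incrementing` / `decrementing` (half-cosine rise / fall, abrupt at the
#' far edge like augmenting and decrementing firing envelopes),
#' `bell` (raised cosine, smooth at both edges), `piecewise` (linear
#' interpolation of `nodes`, a data frame with columns `phi`, `value` on
#' `[0, 1]`).
#'
#' @param shape waveform shape, see above.
#' @param phi_on,phi_off phase window (`0 <= phi_on < phi_off <= phi_on+1`).
#' @param peak,baseline conductance levels, nS (`peak >= baseline >= 0`).
#' @param nodes node table for `shape = "piecewise"`.
#' @return An object of class `"conductance_template"`.
#' @export
conductance_template <- function(shape = c("bell", "ramp", "decrementing",
                                           "incrementing", "constant",
                                           "piecewise"),
                                 phi_on = 0, phi_off = 1, peak = 1,
                                 baseline = 0, nodes = NULL) {
  shape <- match.arg(shape)
  stopifnot(phi_on >= 0, phi_on < 1, phi_off > phi_on,
            phi_off <= phi_on + 1, peak >= baseline, baseline >= 0)
  if (shape == "piecewise" && is.null(nodes)) {
    stop("piecewise shape needs a nodes data frame", call. = FALSE)
  }
  structure(list(shape = shape, phi_on = phi_on, phi_off = phi_off,
                 peak = peak, baseline = baseline, nodes = nodes),
            class = "conductance_template")
}

# evaluate one template at phases phi (vectorized, periodic)
template_value <- function(tmpl, phi) {
  width <- tmpl$phi_off - tmpl$phi_on
  u_raw <- (phi - tmpl$phi_on) %% 1
  inside <- u_raw < width
  u <- u_raw / width
  shp <- switch(tmpl$shape,
    constant = rep(1, length(phi)),
    ramp = u,
    incrementing = (1 - cos(pi * u)) / 2,
    decrementing = (1 + cos(pi * u)) / 2,
    bell = (1 - cos(2 * pi * u)) / 2,
    piecewise = stats::approx(tmpl$nodes$phi, tmpl$nodes$value, xout = u,
                              rule = 2)$y)
  tmpl$baseline + ifelse(inside, (tmpl$peak - tmpl$baseline) * shp, 0)
}

# a conductance input is a template, a list of templates (summed), or a
# plain function of phase
eval_conductance <- function(x, phi) {
  if (is.function(x)) return(x(phi))
  if (inherits(x, "conductance_template")) return(template_value(x, phi))
  if (is.list(x)) {
    return(Reduce(`+`, lapply(x, eval_conductance, phi = phi)))
  }
  if (is.numeric(x) && length(x) == 1L) return(rep(x, length(phi)))
  stop("cannot evaluate conductance input", call. = FALSE)
}

#' Stepwise clamp protocol
#'
#' @param mode `"current_clamp"` (held currents, pA) or `"voltage_clamp"`
#'   (holding potentials, mV).
#' @param levels held levels, one per step; each step lasts
#'   `cycles_per_level` cycles.
#' @param cycles_per_level cycles per held level.
#' @param period cycle period, s.
#' @param sample_rate simulation and recording rate, Hz.
#' @param inspiratory_fraction fraction of the cycle occupied by the
#'   reference burst.
#' @return An object of class `"clamp_protocol"`.
#' @export
clamp_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                           levels = c(-100, -200, -300, -400, -500),
                           cycles_per_level = 10L, period = 3,
                           sample_rate = 12500,
                           inspiratory_fraction = 0.33) {
  mode <- match.arg(mode)
  stopifnot(length(levels) >= 1L, cycles_per_level >= 1L, period > 0,
            sample_rate > 0, inspiratory_fraction > 0,
            inspiratory_fraction < 1)
  structure(list(mode = mode, levels = as.numeric(levels),
                 cycles_per_level = as.integer(cycles_per_level),
                 period = period, sample_rate = sample_rate,
                 inspiratory_fraction = inspiratory_fraction),
            class = "clamp_protocol")
}

# Detector latency of the synthetic reference burst: time from the true
# burst onset to the moment the rectified-integrated envelope crosses the
# threshold fraction of its per-burst amplitude. Computed numerically from
# the deterministic envelope so the generator can advance the envelope and
# make detected onsets coincide with protocol cycle starts.
ref_latency <- function(protocol, tau = 0.05, threshold_frac = 0.10,
                        rise = 0.02) {
  rate <- protocol$sample_rate
  t <- seq(0, 3 * protocol$period - 1 / rate, by = 1 / rate)
  env <- burst_envelope((t %% protocol$period) / protocol$period,
                        protocol$inspiratory_fraction,
                        rise / protocol$period)
  y <- rectify_integrate(env, rate, tau)
  # use the second cycle (integrator settled)
  i0 <- which(t >= protocol$period)[1]
  seg <- y[i0:length(y)]
  amp <- max(seg[seq_len(round(protocol$period * rate))])
  thr <- threshold_frac * amp
  cross <- which(seg[-1] >= thr & seg[-length(seg)] < thr)[1]
  (cross - 1) / rate
}

# smoothed boxcar burst envelope on phase in [0, r)
burst_envelope <- function(phi, r, rise_phase) {
  e <- numeric(length(phi))
  inb <- phi < r
  e[inb] <- 1
  up <- inb & phi < rise_phase
  e[up] <- (1 - cos(pi * phi[up] / rise_phase)) / 2
  down <- inb & phi > r - rise_phase
  e[down] <- (1 + cos(pi * (phi[down] - (r - rise_phase)) / rise_phase)) / 2
  e
}

#' Forward-simulate a rhythmically driven neuron
#'
#' Integrates the passive current-balance model with forward Euler at the
#' protocol sample rate (the step is checked against a tenth of the
#' fastest membrane time constant), under prescribed periodic inhibitory
#' and excitatory conductance waveforms and a stepwise clamp protocol.
#' In current clamp the injected current follows the protocol steps and
#' the membrane potential is integrated; in voltage clamp the potential is
#' held at each level and the recorded current is the ionic current needed
#' to hold it. Optional threshold-reset spiking can be superimposed
#' (current clamp only). Noise is additive white current noise scaled so
#' that the steady-state membrane-potential fluctuation is about
#' `noise_sd` mV (current clamp) or the equivalent clamp-current
#' fluctuation after downsampling to 100 Hz (voltage clamp). The synthetic
#' reference nerve signal is a burst envelope over the inspiratory phase
#' window, advanced by the analytic detector latency so detected onsets
#' coincide with cycle starts, and modulated by rectified white noise when
#' noise is on.
#'
#' @param params a [neuron_params()].
#' @param gi,ge inhibitory / excitatory conductance inputs: a
#'   [conductance_template()], a list of templates (summed), a constant,
#'   or a function of phase.
#' @param protocol a [clamp_protocol()].
#' @param noise_sd mV-equivalent noise standard deviation (0 = noiseless).
#' @param seed integer RNG seed (noise reproducibility).
#' @return A list: `recording` (an [recording()]) and `truth` (class
#'   `"ground_truth"`): `gi_fun`, `ge_fun` (functions of phase),
#'   `gi_bins`, `ge_bins` (sampled on the 100-bin grid), `params`,
#'   `protocol`, `latency`.
#' @export
simulate_neuron <- function(params, gi, ge, protocol, noise_sd = 0,
                            seed = NULL) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "clamp_protocol"))
  rate <- protocol$sample_rate
  dt <- 1 / rate
  n_cycles <- length(protocol$levels) * protocol$cycles_per_level
  n <- round(n_cycles * protocol$period * rate)
  t <- (seq_len(n) - 1L) * dt
  phi <- (t %% protocol$period) / protocol$period
  gi_t <- eval_conductance(gi, phi)
  ge_t <- eval_conductance(ge, phi)
  if (any(gi_t < 0) || any(ge_t < 0)) {
    stop("conductance waveforms must be non-negative", call. = FALSE)
  }
  g_max <- params$g_leak + max(gi_t + ge_t)
  tau_min_ms <- params$C / g_max
  if (dt * 1000 > tau_min_ms / 10) {
    stop(sprintf(
      "Euler step %.3g ms too large for stability (need <= tau_m/10 = %.3g ms)",
      dt * 1000, tau_min_ms / 10), call. = FALSE)
  }
  step_of <- pmin(floor(t / (protocol$period * protocol$cycles_per_level)),
                  length(protocol$levels) - 1L) + 1L
  if (!is.null(seed)) set.seed(as.integer(seed))
  g_bar <- params$g_leak + mean(gi_t) + mean(ge_t)

  if (protocol$mode == "current_clamp") {
    iinj <- protocol$levels[step_of]
    inoise <- if (noise_sd > 0) {
      sigma_i <- noise_sd * sqrt(2 * params$C * g_bar / (dt * 1000))
      stats::rnorm(n, sd = sigma_i)
    } else numeric(0)
    v0 <- (params$g_leak * params$E_leak + gi_t[1] * params$E_i +
             ge_t[1] * params$E_e + iinj[1]) /
      (params$g_leak + gi_t[1] + ge_t[1])
    vm <- euler_vm(gi_t, ge_t, iinj, inoise, params$C, params$g_leak,
                   params$E_leak, params$E_i, params$E_e, v0, dt,
                   params$spike_threshold, params$spike_reset,
                   spike_width = max(1L, round(0.0015 * rate)),
                   spike_amp = 30)
  } else {
    vm <- protocol$levels[step_of]
    g_tot <- params$g_leak + gi_t + ge_t
    iinj <- g_tot * vm - (params$g_leak * params$E_leak +
                            gi_t * params$E_i + ge_t * params$E_e)
    if (noise_sd > 0) {
      sigma_i <- noise_sd * g_bar * sqrt(rate / 100)
      iinj <- iinj + stats::rnorm(n, sd = sigma_i)
    }
  }

  lat <- ref_latency(protocol, threshold_frac = 0.10)
  phi_adv <- ((t + lat) %% protocol$period) / protocol$period
  env <- burst_envelope(phi_adv, protocol$inspiratory_fraction,
                        0.02 / protocol$period)
  ref <- if (noise_sd > 0) env * abs(stats::rnorm(n)) else env * 0.7979

  rec <- recording(t, vm, iinj, ref, rate, protocol$mode,
                   metadata = list(noise_sd = noise_sd,
                                   seed = if (is.null(seed)) NA else seed))
  centers <- (seq_len(100L) - 0.5) / 100
  gi_fun <- function(p) eval_conductance(gi, p)
  ge_fun <- function(p) eval_conductance(ge, p)
  truth <- structure(
    list(gi_fun = gi_fun, ge_fun = ge_fun,
         gi_bins = gi_fun(centers), ge_bins = ge_fun(centers),
         bin_centers = centers, params = params, protocol = protocol,
         latency = lat),
    class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Standard validation fixture
#'
#' The canonical parameter-recovery test case: a neuron with a 10 ms
#' membrane time constant receiving a post-inspiratory/expiratory
#' inhibitory bell (1 to 8 nS over phases 0.33-0.88) and a
#' pre-inspiratory/inspiratory excitatory bell (0.5 to 4 nS over phases
#' 0.88-1.32, wrapping), under a 5-step protocol of 10 cycles per step at
#' a 3 s period. Both waveforms are smooth and slow against the membrane
#' time constant, satisfying the quasi-static assumption, and each is
#' constant over a contiguous part of the cycle so that both wedge
#' boundary lines exist.
#'
#' @param seed RNG seed.
#' @param mode clamp mode.
#' @param noise_sd mV-equivalent noise sd (default 0.5).
#' @param levels held levels (defaults depend on mode).
#' @param cycles_per_level cycles per step.
#' @param params a [neuron_params()].
#' @return As [simulate_neuron()].
#' @export
make_standard_fixture <- function(seed = 1L,
                                  mode = c("current_clamp",
                                           "voltage_clamp"),
                                  noise_sd = 0.5, levels = NULL,
                                  cycles_per_level = 10L,
                                  params = neuron_params()) {
  mode <- match.arg(mode)
  if (is.null(levels)) {
    levels <- if (mode == "current_clamp") {
      c(-100, -200, -300, -400, -500)
    } else {
      c(-100, -90, -80, -70, -60)
    }
  }
  gi <- conductance_template("bell", 0.33, 0.88, peak = 8, baseline = 1)
  ge <- conductance_template("bell", 0.88, 1.32, peak = 4, baseline = 0.5)
  proto <- clamp_protocol(mode, levels = levels,
                          cycles_per_level = cycles_per_level)
  simulate_neuron(params, gi, ge, proto, noise_sd = noise_sd, seed = seed)
}

#' Simulate known-null bin pairs for z-test calibration
#'
#' Generates pairs of phase-bin regressions with identical true total
#' conductance, runs them through the real fitting, error-propagation and
#' significance machinery, and returns the per-pair test results. Under
#' the null (the dynamic component is truly zero) the significant fraction
#' at level alpha should be alpha.
#'
#' @param n_pairs number of null bin pairs.
#' @param levels injected-current levels, pA.
#' @param per_level samples per level in each bin.
#' @param noise_sd voltage fluctuation sd, mV.
#' @param R_true true total resistance, megaohm.
#' @param V0_true true resting potential, mV.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return A data frame `dG_dyn`, `err`, `z`, `p`, `significant`, one row
#'   per pair.
#' @export
simulate_null_bins <- function(n_pairs = 1000L,
                               levels = c(-100, -200, -300, -400, -500),
                               per_level = 30L, noise_sd = 0.5,
                               R_true = 100, V0_true = -70, seed = 1L,
                               alpha = 0.05) {
  set.seed(as.integer(seed))
  i_inj <- rep(levels, each = per_level)
  slope <- R_true / 1e3  # mV/pA
  one_bin <- function() {
    vm <- V0_true + slope * i_inj + stats::rnorm(length(i_inj),
                                                 sd = noise_sd)
    f <- fit_iv_bin(vm, i_inj, "current_clamp")
    G <- 1 / (f$R / 1e3)
    dG <- (f$dR / 1e3) / (f$R / 1e3)^2
    c(G = G, dG = dG)
  }
  out <- vapply(seq_len(n_pairs), function(k) {
    b1 <- one_bin(); b2 <- one_bin()
    dG_dyn <- b1[["G"]] - b2[["G"]]
    err <- dynamic_errors(c(b1[["dG"]], b2[["dG"]]), argmin = 2L)[1]
    c(dG_dyn = dG_dyn, err = err)
  }, c(dG_dyn = 0, err = 0))
  sig <- significance_test(out["dG_dyn", ], out["err", ], alpha = alpha)
  data.frame(dG_dyn = out["dG_dyn", ], err = out["err", ], sig)
}
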