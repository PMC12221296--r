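#' Remove action potentials with a moving median
#'
#' A running median with a window short against the slow synaptic voltage
#' waves but long against a spike suppresses action-potential transients
#' while preserving the slow components the regression needs. Window ends
#' are handled with shrinking windows (no padding with invented values), so
#' the first and last phase bins are not biased by edge artifacts.
#'
#' @param vm voltage series, mV.
#' @param sample_rate sampling rate of `vm`, Hz.
#' @param window median window length, s (default 0.1 s).
#' @return Filtered series of the same length.
#' @export
remove_spikes <- function(vm, sample_rate, window = 0.1) {
  k <- floor(window * sample_rate)
  if (k < 3L) {
    stop("median window spans fewer than 3 samples at this rate",
         call. = FALSE)
  }
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= length(vm)) k <- length(vm) - (1L - length(vm) %% 2L)
  as.numeric(stats::runmed(vm, k = k, endrule = "median"))
}

#' Downsample a trace by block averaging
#'
#' Averages consecutive blocks of `from_rate / to_rate` samples. Block
#' averaging is an implicit anti-alias filter and preserves the trace mean
#' exactly; applied to the time channel it returns block-center times.
#' Trailing samples that do not fill a block are dropped.
#'
#' @param x trace values.
#' @param from_rate original sampling rate, Hz.
#' @param to_rate target sampling rate, Hz; must divide `from_rate`.
#' @return Downsampled vector of length `floor(length(x) * to_rate/from_rate)`.
#' @export
downsample_trace <- function(x, from_rate, to_rate) {
  if (to_rate > from_rate) {
    stop("to_rate must not exceed from_rate", call. = FALSE)
  }
  ratio <- from_rate / to_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf("from_rate/to_rate must be an integer (got %g/%g)",
                 from_rate, to_rate), call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(as.numeric(x))
  n_blk <- length(x) %/% ratio
  if (n_blk < 1L) stop("trace shorter than one downsampling block",
                       call. = FALSE)
  colMeans(matrix(x[seq_len(n_blk * ratio)], nrow = ratio))
}

#' Rectify and integrate a nerve signal
#'
#' Full-wave rectification followed by a first-order leaky integrator,
#' `y[k] = y[k-1] + (dt/tau) * (|x[k]| - y[k-1])` with `y[1] = |x[1]|`,
#' emulating the standard analog conditioning of nerve recordings.
#'
#' @param x raw reference signal.
#' @param sample_rate sampling rate, Hz.
#' @param tau integrator time constant, s (default 0.05 s); must exceed the
#'   sample interval.
#' @return Non-negative integrated envelope, same length as `x`.
#' @export
rectify_integrate <- function(x, sample_rate, tau = 0.05) {
  dt <- 1 / sample_rate
  if (tau <= dt) stop("tau must exceed the sample interval", call. = FALSE)
  a <- dt / tau
  ax <- abs(x)
  # y[k] = (1-a) y[k-1] + a |x[k]|, seeded at |x[1]|
  y <- stats::filter(a * ax[-1], 1 - a, method = "recursive", init = ax[1])
  c(ax[1], as.numeric(y))
}

#' Cycle set: burst onsets and per-cycle periods
#'
#' @param onsets strictly increasing burst-onset times, s.
#' @param inspiratory_fraction estimated fraction of the cycle occupied by
#'   the reference burst.
#' @return An object of class `"cycle_set"` with elements `onsets`,
#'   `periods`, `cv_period`, `inspiratory_fraction`.
#' @export
cycle_set <- function(onsets, inspiratory_fraction = NA_real_) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L || any(diff(onsets) <= 0)) {
    stop("onsets must be at least 2 strictly increasing times",
         call. = FALSE)
  }
  periods <- diff(onsets)
  cv <- if (length(periods) > 1L) {
    stats::sd(periods) / mean(periods)
  } else 0
  structure(list(onsets = onsets, periods = periods, cv_period = cv,
                 inspiratory_fraction = inspiratory_fraction),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf(
    "<cycle_set> %d cycles, mean period %.3f s, CV %.3f, burst fraction %s\n",
    length(x$periods), mean(x$periods), x$cv_period,
    ifelse(is.na(x$inspiratory_fraction), "NA",
           sprintf("%.2f", x$inspiratory_fraction))))
  invisible(x)
}

#' Detect burst onsets in an integrated reference signal
#'
#' The onset of a burst is the upward crossing of
#' `baseline + threshold_frac * (amplitude - baseline)`, where the baseline
#' is the 5th percentile of the integrated signal and the amplitude is the
#' median of per-burst peaks. Detection is iterated once: a provisional pass
#' uses the global maximum as amplitude, the refined pass the median of the
#' per-burst peaks found provisionally (robust to a single large burst).
#' Crossing times are refined by linear interpolation between samples, and
#' crossings closer than `min_interval` to the previous onset are suppressed
#' (default: half the median provisional period).
#'
#' @param x integrated reference signal (see [rectify_integrate()]).
#' @param sample_rate sampling rate, Hz.
#' @param threshold_frac onset threshold fraction (default 0.10).
#' @param min_interval minimal onset separation, s, or `NULL` for the
#'   automatic default.
#' @param t0 time of the first sample, s.
#' @return A [cycle_set()].
#' @export
detect_burst_onsets <- function(x, sample_rate, threshold_frac = 0.10,
                                min_interval = NULL, t0 = 0) {
  x <- as.numeric(x)
  baseline <- stats::quantile(x, 0.05, names = FALSE)
  find_crossings <- function(thr, min_gap) {
    up <- which(x[-1] >= thr & x[-length(x)] < thr)
    if (!length(up)) return(numeric(0))
    frac <- (thr - x[up]) / (x[up + 1L] - x[up])
    tc <- t0 + (up - 1L + frac) / sample_rate
    if (min_gap > 0 && length(tc) > 1L) {
      keep <- c(TRUE, diff(tc) >= min_gap)
      # re-apply sequentially so suppressed crossings do not reset the gap
      kept <- tc[1]
      for (v in tc[-1]) if (v - kept[length(kept)] >= min_gap) {
        kept <- c(kept, v)
      }
      tc <- kept
    }
    tc
  }
  amp0 <- max(x)
  if (amp0 - baseline <= 0) {
    stop("burst detection failed: flat reference signal", call. = FALSE)
  }
  thr0 <- baseline + threshold_frac * (amp0 - baseline)
  prov <- find_crossings(thr0, 0)
  if (length(prov) < 2L) {
    stop("burst detection failed: fewer than 2 onsets found", call. = FALSE)
  }
  if (is.null(min_interval)) {
    min_interval <- 0.5 * stats::median(diff(prov))
  }
  # per-burst peaks between provisional onsets
  idx <- pmax(1L, floor((prov - t0) * sample_rate) + 1L)
  bounds <- c(idx, length(x))
  peaks <- vapply(seq_len(length(bounds) - 1L), function(k)
    max(x[bounds[k]:bounds[k + 1L]]), 0)
  amp <- stats::median(peaks)
  thr <- baseline + threshold_frac * (amp - baseline)
  onsets <- find_crossings(thr, min_interval)
  if (length(onsets) < 2L) {
    stop("burst detection failed: fewer than 2 onsets found", call. = FALSE)
  }
  above <- mean(x >= thr)
  cycle_set(onsets, inspiratory_fraction = above)
}

#' Assign cycle phases to sample times
#'
#' The phase is a piece-wise linear function of time:
#' `phi(t) = (t - t_k) / (t_{k+1} - t_k)` for `t` between consecutive burst
#' onsets `t_k` and `t_{k+1}`; `phi = 0` exactly at each onset. Samples
#' outside `[first onset, last onset)` get `NA` (excluded).
#'
#' @param t sample times, s.
#' @param cycles a [cycle_set()].
#' @return A list with `phase` (in `[0, 1)`, `NA` outside the span) and
#'   `cycle` (1-based cycle index, `NA` outside).
#' @export
compute_phase <- function(t, cycles) {
  on <- cycles$onsets
  k <- findInterval(t, on)
  inside <- k >= 1L & k < length(on)
  if (!any(inside)) {
    stop("no samples fall within the detected cycles", call. = FALSE)
  }
  phase <- rep(NA_real_, length(t))
  kk <- k[inside]
  phase[inside] <- (t[inside] - on[kk]) / (on[kk + 1L] - on[kk])
  cyc <- ifelse(inside, k, NA_integer_)
  list(phase = phase, cycle = cyc)
}

# Identify maximal runs where the controlled channel stays within the
# plateau tolerance. Returns an integer run id per sample plus a per-run
# summary (level value, duration).
identify_steps <- function(x, time, tolerance) {
  jump <- abs(diff(x)) > tolerance
  run <- cumsum(c(1L, as.integer(jump)))
  levels <- tapply(x, run, stats::median)
  dur <- tapply(time, run, function(tt) diff(range(tt)))
  n <- tabulate(run)
  list(run = run,
       table = data.frame(run = as.integer(names(levels)),
                          level = as.numeric(levels),
                          duration = as.numeric(dur),
                          n_samples = n))
}

#' Epoch quality control
#'
#' Evaluates the acceptance criteria for an analysis epoch: (1) the
#' coefficient of variation of the cycle period must be below `cv_max`;
#' (2) at least `min_steps` held current (or command-voltage) steps, each
#' held for at least `min_cycles_per_step` cycles; (3) no baseline drift
#' beyond `drift_max` mV/min (linear trend of the per-cycle inter-burst
#' baseline potential after removing step offsets). All criteria are
#' reported; `passed` is `TRUE` iff no criterion failed.
#'
#' @param prep a preprocessed epoch from [preprocess_recording()], or a
#'   recording (which is preprocessed first).
#' @param config an [sc_config()].
#' @return An object of class `"qc_report"`: `passed`, `cv_period`,
#'   `n_steps`, `cycles_per_step`, `drift_mv_min`, `drift_flag`, `reasons`.
#' @export
qc_epoch <- function(prep, config = sc_config()) {
  if (inherits(prep, "sc_recording")) {
    prep <- preprocess_recording(prep, config)
  }
  reasons <- character(0)
  cv <- prep$cycles$cv_period
  if (!(cv < config$cv_max)) {
    reasons <- c(reasons, sprintf("cv_period: %.3f >= %.3f", cv,
                                  config$cv_max))
  }
  med_period <- stats::median(prep$cycles$periods)
  steps <- prep$steps$table
  # duration from the sample count; a tenth-of-a-cycle tolerance absorbs
  # the one-sample boundary effects of downsampling and step transitions
  cyc_per_step <- (steps$n_samples / prep$sample_rate) / med_period
  qualifying <- sum(cyc_per_step >= config$min_cycles_per_step - 0.1)
  if (qualifying < config$min_steps) {
    reasons <- c(reasons, sprintf(
      "min_steps: %d step(s) held >= %d cycles, need %d", qualifying,
      config$min_cycles_per_step, config$min_steps))
  }
  drift <- baseline_drift(prep)
  drift_flag <- is.finite(drift) && abs(drift) > config$drift_max
  if (drift_flag) {
    reasons <- c(reasons, sprintf("drift: |%.2f| mV/min > %.2f", drift,
                                  config$drift_max))
  }
  structure(list(passed = length(reasons) == 0L, cv_period = cv,
                 n_steps = qualifying,
                 cycles_per_step = as.numeric(cyc_per_step),
                 drift_mv_min = drift, drift_flag = drift_flag,
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("  cv_period %.3f | %d qualifying steps | drift %.2f mV/min\n",
              x$cv_period, x$n_steps, x$drift_mv_min))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  invisible(x)
}

# Linear trend (mV/min) of the per-cycle inter-burst baseline of the
# measured channel, with per-step offsets removed. In voltage clamp the
# measured channel is the current; its trend is converted to an equivalent
# voltage drift through the median total conductance.
baseline_drift <- function(prep) {
  measured <- if (prep$clamp_mode == "current_clamp") prep$vm else prep$i_inj
  expir <- !is.na(prep$phase) &
    prep$phase >= (prep$cycles$inspiratory_fraction %||% 0.33)
  if (sum(expir) < 4L) return(NA_real_)
  cyc <- prep$cycle[expir]
  base <- tapply(measured[expir], cyc, stats::median)
  tmid <- tapply(prep$time[expir], cyc, stats::median)
  run <- tapply(prep$steps$run[expir], cyc, function(r)
    as.integer(names(which.max(table(r)))))
  if (length(base) < 3L) return(NA_real_)
  df <- data.frame(y = as.numeric(base), t = as.numeric(tmid),
                   run = factor(as.integer(run)))
  fit <- if (nlevels(df$run) > 1L) {
    stats::lm(y ~ t + run, data = df)
  } else {
    stats::lm(y ~ t, data = df)
  }
  slope <- stats::coef(fit)[["t"]] * 60  # per second -> per minute
  if (prep$clamp_mode == "voltage_clamp") {
    # pA/min -> mV/min through a coarse conductance scale
    g_scale <- stats::median(abs(diff(range(prep$i_inj))) /
                               max(diff(range(prep$vm)), 1))
    if (is.finite(g_scale) && g_scale > 0) slope <- slope / g_scale
  }
  slope
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Preprocess a recording into an analysis-ready epoch
#'
#' Runs the full conditioning chain: moving-median spike removal on the
#' measured channel, block-average downsampling of all traces to the
#' analysis rate, rectification and leaky integration of the reference
#' signal, burst-onset detection, phase assignment, held-step
#' identification on the controlled channel, and exclusion flagging
#' (samples outside the cycle span, inside post-step transients, or outside
#' the hyperpolarized voltage window).
#'
#' @param rec an [recording()].
#' @param config an [sc_config()].
#' @return An object of class `"sc_prep"`: downsampled `time`, `vm`,
#'   `i_inj`, `ref_int`, `phase`, `cycle`, per-sample `steps$run`,
#'   logical `included`, the detected [cycle_set()] in `cycles`, and
#'   `clamp_mode`.
#' @export
preprocess_recording <- function(rec, config = sc_config()) {
  validate_recording(rec)
  raw_rate <- rec$sample_rate
  measured <- if (rec$clamp_mode == "current_clamp") "vm" else "i_inj"
  filtered <- rec
  filtered[[measured]] <- remove_spikes(rec[[measured]], raw_rate,
                                        config$median_window)
  ref_int_raw <- rectify_integrate(rec$ref, raw_rate, config$integrator_tau)

  to <- config$target_rate
  time <- downsample_trace(rec$time, raw_rate, to)
  vm <- downsample_trace(filtered$vm, raw_rate, to)
  i_inj <- downsample_trace(filtered$i_inj, raw_rate, to)
  ref_int <- downsample_trace(ref_int_raw, raw_rate, to)

  cycles <- detect_burst_onsets(ref_int, to,
                                threshold_frac = config$burst_threshold_frac,
                                t0 = time[1])
  ph <- compute_phase(time, cycles)

  controlled <- if (rec$clamp_mode == "current_clamp") i_inj else vm
  tol <- if (rec$clamp_mode == "current_clamp") config$step_tolerance else
    config$step_tolerance / 5  # mV plateaus are tighter than pA plateaus
  steps <- identify_steps(controlled, time, tol)

  # transient exclusion after each step boundary
  boundary_t <- tapply(time, steps$run, min)
  trans <- rep(FALSE, length(time))
  for (bt in boundary_t[-1]) {
    trans <- trans | (time >= bt & time < bt + config$transient_window)
  }
  in_window <- vm >= config$v_window[1] & vm <= config$v_window[2]
  included <- !is.na(ph$phase) & !trans & in_window

  structure(list(time = time, vm = vm, i_inj = i_inj, ref_int = ref_int,
                 phase = ph$phase, cycle = ph$cycle, steps = steps,
                 included = included, cycles = cycles,
                 clamp_mode = rec$clamp_mode, sample_rate = to,
                 config = config),
            class = "sc_prep")
}
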