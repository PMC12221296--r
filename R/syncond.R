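#' Reconstruct phase-resolved synaptic conductance profiles
#'
#' The package's main fitting function. Runs the full reconstruction on an
#' intracellular recording from a rhythmically active neuron: trace
#' preprocessing and quality control, phase-binned current-voltage
#' regression, wedge-diagram reversal-potential estimation, decomposition
#' of the total conductance into inhibitory and excitatory components
#' with dynamic-component errors and one-tailed z-tests, and (optionally)
#' functional-connectome motif inference.
#'
#' Reversal potentials: user-supplied values always win; otherwise the
#' inhibitory reversal comes from the wedge upper boundary (falling back
#' to `config$e_i_fallback` if estimation fails) and the excitatory
#' reversal from the wedge lower boundary when an admissible one exists,
#' else `config$e_e_default`. The wedge fit is always reported for
#' comparison.
#'
#' The whole pipeline is deterministic: the same recording and
#' configuration give bit-identical results.
#'
#' @param rec an [recording()].
#' @param config an [sc_config()].
#' @param reversals optional [reversal_pair()] overriding estimation.
#' @param phenotype optional phenotype name of the recorded neuron; when
#'   given, a motif report is attached.
#' @param windows optional [phase_windows()]; default derives the
#'   inspiratory fraction from the reference-burst duty cycle.
#' @param force proceed despite a failed quality control.
#' @return An object of class `"syncond"`: `profile` (the per-bin
#'   [conductance_profile()]), `regression`, `conductance`, `wedge`,
#'   `reversals` (values used and their source), `qc`, `cycles`,
#'   `windows`, `labels`, `motifs` (or `NULL`), `g_leak_est`, `config`,
#'   `clamp_mode`.
#' @export
#' @examples
#' \donttest{
#' sim <- make_standard_fixture(seed = 1)
#' fit <- syncond(sim$recording)
#' summary(fit)
#' }
syncond <- function(rec, config = sc_config(), reversals = NULL,
                    phenotype = NULL, windows = NULL, force = FALSE) {
  prep <- preprocess_recording(rec, config)
  qc <- qc_epoch(prep, config)
  if (!qc$passed && !force) {
    stop(paste0("epoch failed quality control: ",
                paste(qc$reasons, collapse = "; "),
                " (use force = TRUE to override)"), call. = FALSE)
  }
  reg <- phase_regression(prep, config)
  G_tab <- total_conductance(reg)
  wedge <- fit_wedge(G_tab$G, reg$V0, valid = G_tab$valid, config,
                     dG = G_tab$dG, dV0 = reg$dV0)

  if (!is.null(reversals)) {
    if (!inherits(reversals, "reversal_pair")) {
      reversals <- reversal_pair(reversals[[1]], reversals[[2]])
    }
    rev_used <- reversals
    rev_source <- "user"
  } else {
    e_i <- if (wedge$e_i_ok) wedge$e_i_hat else config$e_i_fallback
    rev_used <- reversal_pair(e_i, wedge$e_e_hat)
    rev_source <- paste0(
      if (wedge$e_i_ok) "wedge" else "fallback", "/",
      if (wedge$e_e_defaulted) "default" else "wedge")
  }
  profile <- conductance_profile(G_tab, reg$V0, rev_used, config)

  if (is.null(windows)) {
    r <- prep$cycles$inspiratory_fraction
    if (!is.finite(r) || r <= 0.05 || r >= 0.95) r <- 0.33
    windows <- phase_windows(r)
  }
  labels <- classify_inputs(profile, windows, min_frac = 0.25)
  motifs <- if (!is.null(phenotype)) {
    infer_motif(profile, target = phenotype, windows = windows,
                labels = labels)
  }
  structure(list(profile = profile, regression = reg,
                 conductance = G_tab, wedge = wedge,
                 reversals = list(e_i = rev_used$e_i, e_e = rev_used$e_e,
                                  source = rev_source),
                 qc = qc, cycles = prep$cycles, windows = windows,
                 labels = labels, motifs = motifs,
                 g_leak_est = attr(profile, "g_leak_est"),
                 config = config, clamp_mode = rec$clamp_mode),
            class = "syncond")
}

#' @export
print.syncond <- function(x, ...) {
  n_valid <- sum(x$profile$valid)
  cat(sprintf(
    "<syncond> %s, %d cycles, %d/%d valid phase bins\n",
    gsub("_", " ", x$clamp_mode), length(x$cycles$periods),
    n_valid, nrow(x$profile)))
  cat(sprintf("  g_leak estimate: %.2f nS\n", x$g_leak_est))
  cat(sprintf("  reversals used: Ei = %.1f mV, Ee = %.1f mV (%s)\n",
              x$reversals$e_i, x$reversals$e_e, x$reversals$source))
  invisible(x)
}

#' @export
summary.syncond <- function(object, ...) {
  p <- object$profile
  v <- p$valid
  out <- list(
    n_bins = nrow(p), n_valid = sum(v),
    n_cycles = length(object$cycles$periods),
    cv_period = object$cycles$cv_period,
    qc_passed = object$qc$passed,
    g_leak_est = object$g_leak_est,
    e_i = object$reversals$e_i, e_e = object$reversals$e_e,
    rev_source = object$reversals$source,
    peak_dGi = max(p$dGi_dyn[v]), peak_dGe = max(p$dGe_dyn[v]),
    frac_sig_i = mean(p$sig_i[v]), frac_sig_e = mean(p$sig_e[v]),
    labels = object$labels)
  class(out) <- "summary.syncond"
  out
}

#' @export
print.summary.syncond <- function(x, ...) {
  cat("Phase-resolved synaptic conductance reconstruction\n")
  cat(sprintf("  %d phase bins (%d valid), %d cycles, period CV %.3f, QC %s\n",
              x$n_bins, x$n_valid, x$n_cycles, x$cv_period,
              if (x$qc_passed) "passed" else "FAILED"))
  cat(sprintf("  leak estimate %.2f nS; Ei %.1f mV, Ee %.1f mV (%s)\n",
              x$g_leak_est, x$e_i, x$e_e, x$rev_source))
  cat(sprintf("  peak dGi %.2f nS (%.0f%% bins significant); peak dGe %.2f nS (%.0f%% bins significant)\n",
              x$peak_dGi, 100 * x$frac_sig_i, x$peak_dGe,
              100 * x$frac_sig_e))
  lab <- x$labels[x$labels$present, , drop = FALSE]
  if (nrow(lab)) {
    cat("  inputs by phase window:\n")
    for (k in seq_len(nrow(lab))) {
      cat(sprintf("    %-7s %-10s peak %.2f nS at phase %.2f\n",
                  lab$window[k], lab$sign[k], lab$peak[k],
                  lab$peak_phase[k]))
    }
  }
  invisible(x)
}

#' @export
coef.syncond <- function(object, ...) {
  c(g_leak = object$g_leak_est, e_i = object$reversals$e_i,
    e_e = object$reversals$e_e)
}

#' @export
as.data.frame.syncond <- function(x, ...) {
  out <- x$profile
  class(out) <- "data.frame"
  out
}

#' Plot a conductance reconstruction
#'
#' `which = "profile"` draws the dynamic inhibitory (blue) and excitatory
#' (red) conductance components over two cycles with error envelopes;
#' `which = "wedge"` draws the `(G, I0)` trajectory with the fitted
#' boundary lines.
#'
#' @param x a [syncond()] fit.
#' @param which `"profile"` or `"wedge"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.syncond <- function(x, which = c("profile", "wedge"), ...) {
  which <- match.arg(which)
  p <- x$profile
  if (which == "profile") {
    ph <- c(p$phase_center, p$phase_center + 1)
    gi <- rep(p$dGi_dyn, 2); ge <- rep(p$dGe_dyn, 2)
    ei <- rep(p$err_i, 2); ee <- rep(p$err_e, 2)
    ylim <- range(0, gi + ei, ge + ee, na.rm = TRUE)
    graphics::plot(ph, gi, type = "l", col = "blue", lwd = 2,
                   xlab = "cycle phase", ylab = "dynamic conductance (nS)",
                   ylim = ylim, ...)
    graphics::lines(ph, ge, col = "red", lwd = 2)
    ok <- is.finite(gi)
    graphics::arrows(ph[ok], (gi - ei)[ok], ph[ok], (gi + ei)[ok],
                     length = 0, col = grDevices::adjustcolor("blue", 0.3))
    ok <- is.finite(ge)
    graphics::arrows(ph[ok], (ge - ee)[ok], ph[ok], (ge + ee)[ok],
                     length = 0, col = grDevices::adjustcolor("red", 0.3))
    graphics::abline(v = 1, lty = 3)
    graphics::legend("topright", legend = c("inhibitory", "excitatory"),
                     col = c("blue", "red"), lwd = 2, bty = "n")
  } else {
    tr <- x$wedge$trajectory
    graphics::plot(tr$G, tr$I0, pch = 3, col = "red",
                   xlab = "total conductance G (nS)",
                   ylab = expression(I[0] ~ "(pA)"), ...)
    if (!is.null(x$wedge$upper)) {
      graphics::abline(x$wedge$upper$intercept, x$wedge$upper$slope,
                       lwd = 2)
    }
    if (!is.null(x$wedge$lower)) {
      graphics::abline(x$wedge$lower$intercept, x$wedge$lower$slope,
                       lwd = 2)
    }
  }
  invisible(x)
}
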