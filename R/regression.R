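#' Assign phase values to bins
#'
#' Bin `i` (1-based) receives samples with phase in the right-open interval
#' `[(i-1)/n, i/n)`, so the bins partition `[0, 1)` with no double counting.
#'
#' @param phase phases in `[0, 1)`; `NA` allowed (stays `NA`).
#' @param n_bins number of bins.
#' @return A list with integer `bin` per sample and numeric `centers`
#'   (bin midpoints `(phi_i + phi_{i+1}) / 2`).
#' @export
bin_by_phase <- function(phase, n_bins) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  ok <- !is.na(phase)
  if (any(phase[ok] < 0 | phase[ok] >= 1)) {
    stop("phases must lie in [0, 1)", call. = FALSE)
  }
  bin <- rep(NA_integer_, length(phase))
  # nudge against representation error so grid phases land in their bin
  bin[ok] <- pmin(floor(phase[ok] * n_bins + 1e-9), n_bins - 1L) + 1L
  list(bin = bin, centers = (seq_len(n_bins) - 0.5) / n_bins)
}

#' Fit the per-bin current-voltage relation
#'
#' In current clamp the measured potential is regressed on the controlled
#' current, `Vm = V0 + R * Iinj`: the slope is the total resistance and the
#' intercept the effective resting potential for that phase. In voltage
#' clamp the measured current is regressed on the controlled potential,
#' `I = G * (Vm - V0)`: the slope is the total conductance and the result is
#' converted to `(R, V0)` with first-order error propagation (including the
#' slope-intercept covariance). Regressing the measured quantity on the
#' controlled one keeps the least-squares assumptions in both modes.
#'
#' Units: mV and pA in, so the raw slope is in gigaohm; `R` is reported in
#' megaohm.
#'
#' @param vm membrane (or command) potentials in the bin, mV.
#' @param i_inj matched currents, pA.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param n_min minimal sample count.
#' @param levels optional per-sample held-level ids used to count distinct
#'   levels; when `NULL`, distinct controlled-channel values (within 1e-6)
#'   are counted.
#' @return A list `R` (megaohm), `V0` (mV), `dR`, `dV0`, `n`, `n_levels`,
#'   `valid`, `resid_sd`. Rank-deficient bins (a single level) come back
#'   with `valid = FALSE`, not an error.
#' @export
fit_iv_bin <- function(vm, i_inj, mode = c("current_clamp", "voltage_clamp"),
                       n_min = 10L, levels = NULL) {
  mode <- match.arg(mode)
  invalid <- list(R = NA_real_, V0 = NA_real_, dR = NA_real_,
                  dV0 = NA_real_, n = length(vm), n_levels = 0L,
                  valid = FALSE, resid_sd = NA_real_)
  n <- length(vm)
  if (n < n_min) return(invalid)
  controlled <- if (mode == "current_clamp") i_inj else vm
  n_levels <- if (!is.null(levels)) {
    length(unique(levels))
  } else {
    length(unique(round(controlled / 1e-6)))
  }
  invalid$n_levels <- n_levels
  if (n_levels < 2L || stats::sd(controlled) == 0) return(invalid)

  if (mode == "current_clamp") {
    f <- ols_line(i_inj, vm)
    slope_gohm <- f$slope                      # mV/pA = GOhm
    if (!is.finite(slope_gohm) || slope_gohm == 0) return(invalid)
    R <- slope_gohm * 1e3                      # MOhm
    V0 <- f$intercept
    dR <- f$se_slope * 1e3
    dV0 <- f$se_intercept
  } else {
    f <- ols_line(vm, i_inj)
    G <- f$slope                               # pA/mV = nS
    if (!is.finite(G) || G == 0) return(invalid)
    a <- f$intercept                           # pA; a = -G * V0
    R <- 1e3 / G                               # MOhm
    V0 <- -a / G
    dR <- 1e3 * f$se_slope / G^2
    # var(V0) by the delta method, with cov(a, G)
    dV0 <- sqrt((f$se_intercept / G)^2 + (a * f$se_slope / G^2)^2 -
                  2 * (a / G^3) * f$cov_ab)
  }
  list(R = R, V0 = V0, dR = dR, dV0 = dV0, n = n, n_levels = n_levels,
       valid = TRUE, resid_sd = f$resid_sd)
}

# plain least-squares line y = a + b x with classical standard errors;
# kept as the single regression kernel for the per-bin fits
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  b <- sxy / sxx
  a <- my - b * mx
  res <- y - a - b * x
  s2 <- sum(res^2) / max(n - 2L, 1L)
  se_b <- sqrt(s2 / sxx)
  se_a <- sqrt(s2 * (1 / n + mx^2 / sxx))
  list(slope = b, intercept = a, se_slope = se_b, se_intercept = se_a,
       cov_ab = -mx * s2 / sxx, resid_sd = sqrt(s2))
}

#' Phase-binned regression table
#'
#' Pools all included samples of an epoch by phase bin (across every cycle
#' and current step) and fits the per-bin current-voltage relation.
#'
#' @param prep a preprocessed epoch from [preprocess_recording()].
#' @param config an [sc_config()].
#' @return A data frame of class `"phase_regression"`, one row per bin:
#'   `phase_center`, `R` (megaohm), `V0` (mV), `dR`, `dV0`, `n_samples`,
#'   `n_levels`, `valid`.
#' @export
phase_regression <- function(prep, config = sc_config()) {
  bb <- bin_by_phase(prep$phase, config$n_bins)
  rows <- vector("list", config$n_bins)
  for (i in seq_len(config$n_bins)) {
    sel <- prep$included & !is.na(bb$bin) & bb$bin == i
    f <- fit_iv_bin(prep$vm[sel], prep$i_inj[sel], prep$clamp_mode,
                    n_min = config$n_min, levels = prep$steps$run[sel])
    if (f$valid && f$R <= 0) {
      # nonphysical resistance: invalidate, never report a negative G later
      f$valid <- FALSE
    }
    rows[[i]] <- data.frame(phase_center = bb$centers[i], R = f$R,
                            V0 = f$V0, dR = f$dR, dV0 = f$dV0,
                            n_samples = f$n, n_levels = f$n_levels,
                            valid = f$valid)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phase_regression", "data.frame")
  out
}

#' Total conductance from the regression table
#'
#' `G = 1/R` with the standard error `dG = dR / R^2`; the megaohm slope is
#' converted so that `G` comes out in nS. Invalid bins propagate as flagged
#' missing values, never interpolated.
#'
#' @param table a [phase_regression()] table.
#' @return A data frame `phase_center`, `G` (nS), `dG` (nS), `valid`.
#' @export
total_conductance <- function(table) {
  R_gohm <- table$R / 1e3
  dR_gohm <- table$dR / 1e3
  valid <- table$valid & is.finite(R_gohm) & R_gohm > 0
  G <- ifelse(valid, 1 / R_gohm, NA_real_)
  dG <- ifelse(valid, dR_gohm / R_gohm^2, NA_real_)
  data.frame(phase_center = table$phase_center, G = G, dG = dG,
             valid = valid)
}
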