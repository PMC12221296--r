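#' Phase-resolved zero-current intercept
#'
#' `I0 = -G * V0`, the current axis intercept of the per-bin I-V line.
#' With `G` in nS and `V0` in mV the product is in pA.
#'
#' @param G per-bin total conductance, nS.
#' @param V0 per-bin effective resting potential, mV.
#' @return Per-bin `I0`, pA.
#' @export
compute_I0 <- function(G, V0) -G * V0

# Enumerate contiguous (circular) bin windows, fit I0 ~ G on each, and pick
# the best boundary by score = length * R^2 subject to three requirements:
# (1) R^2 >= min_r2; (2) tightness -- the window's residual scale must be
# at the I0 measurement-error scale (2x the median per-bin I0 error, with
# a 2%-of-range floor), which stops long windows that straddle the wedge
# interior from outscoring the true boundary segment; (2b) lever arm --
# the window must span at least a quarter of the trajectory's G range,
# since a slope fitted on a near-degenerate abscissa range is not an
# identifiable reversal-potential estimate; (3) one-sided
# containment -- every trajectory point must lie on or below (upper
# boundary; mirrored for lower) the fitted line within 2x the residual
# scale. Contiguity in phase reflects that zero-excitation (or
# zero-inhibition) intervals are contiguous parts of the cycle.
boundary_search <- function(G, I0, side = c("upper", "lower"),
                            min_len = 5L, min_r2 = 0.9, sigma_I0 = NULL,
                            min_span = 0.25) {
  side <- match.arg(side)
  ok <- which(is.finite(G) & is.finite(I0))
  n <- length(ok)
  if (n < min_len) return(NULL)
  x <- G[ok]; y <- I0[ok]
  tight_tol <- max(0.02 * diff(range(y)),
                   if (!is.null(sigma_I0)) {
                     2 * stats::median(sigma_I0[ok], na.rm = TRUE)
                   } else 0,
                   na.rm = TRUE)
  if (!is.finite(tight_tol) || tight_tol <= 0) tight_tol <- Inf
  # circular windows via doubled arrays and cumulative sums
  x2 <- c(x, x); y2 <- c(y, y)
  cx <- cumsum(c(0, x2)); cy <- cumsum(c(0, y2))
  cxx <- cumsum(c(0, x2^2)); cyy <- cumsum(c(0, y2^2))
  cxy <- cumsum(c(0, x2 * y2))
  max_len <- max(min_len, n - 2L)
  cand <- list()
  for (len in seq(min_len, max_len)) {
    s <- seq_len(n)             # window start positions (circular)
    e <- s + len - 1L
    sx <- cx[e + 1L] - cx[s];  sy <- cy[e + 1L] - cy[s]
    sxx <- cxx[e + 1L] - cxx[s]; syy <- cyy[e + 1L] - cyy[s]
    sxy <- cxy[e + 1L] - cxy[s]
    vx <- sxx - sx^2 / len
    vy <- syy - sy^2 / len
    vxy <- sxy - sx * sy / len
    slope <- ifelse(vx > 0, vxy / vx, NA_real_)
    r2 <- ifelse(vx > 0 & vy > 0, vxy^2 / (vx * vy), NA_real_)
    pass <- !is.na(r2) & r2 >= min_r2
    if (any(pass)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = s[pass], len = len, slope = slope[pass],
        intercept = (sy[pass] - slope[pass] * sx[pass]) / len,
        r2 = r2[pass], score = len * r2[pass])
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), , drop = FALSE]
  sgn <- if (side == "upper") 1 else -1
  for (k in seq_len(nrow(cand))) {
    w <- cand[k, ]
    widx <- ((w$start - 1L + seq_len(w$len) - 1L) %% n) + 1L
    if (diff(range(x[widx])) < min_span * diff(range(x))) next
    res <- y[widx] - (w$intercept + w$slope * x[widx])
    if (stats::sd(res) > tight_tol) next
    tol <- 2 * max(stats::sd(res), 1e-8 * max(diff(range(y)), 1))
    # containment: every trajectory point on the correct side of the line
    dev <- sgn * (y - (w$intercept + w$slope * x))
    if (all(dev <= tol)) {
      se <- boundary_se(x[widx], y[widx])
      return(list(slope = w$slope, intercept = w$intercept, r2 = w$r2,
                  se_slope = se$se_slope, se_intercept = se$se_intercept,
                  bins = ok[widx], n_bins = w$len, tol = tol,
                  contained = TRUE))
    }
  }
  NULL
}

boundary_se <- function(x, y) {
  f <- ols_line(x, y)
  list(se_slope = f$se_slope, se_intercept = f$se_intercept)
}

#' Wedge-diagram fit: reversal potentials from boundary lines
#'
#' The per-cycle trajectory of `(G(phi), I0(phi))` points is bounded above
#' by the zero-excitation line `I0 = -Ei * G - Ge0 * (Ee - Ei)` and below
#' by the zero-inhibition line `I0 = -Ee * G + Gi0 * (Ee - Ei)`, where
#' `Ge0`, `Gi0` are the static (minimal) synaptic components. During phases
#' where the neuron receives only phase-dependent inhibition the trajectory
#' moves along the upper line, whose slope is `-Ei`; during pure-excitation
#' phases along the lower line with slope `-Ee`. Fitting the nearly linear
#' boundary portions therefore estimates the reversal potentials.
#'
#' The lower-line estimate is accepted only when its implied `Ee` falls in
#' the plausibility window and the fit quality is adequate; otherwise the
#' conventional default `e_e_default` is returned with the `defaulted`
#' flag. No plausibility clamp is imposed on `Ei` (empirically estimates
#' span tens of mV).
#'
#' @param G,V0 per-bin total conductance (nS) and resting potential (mV).
#' @param valid logical validity per bin.
#' @param config an [sc_config()] (boundary thresholds, defaults).
#' @param dG,dV0 optional per-bin standard errors (nS, mV) used to set the
#'   boundary-tightness scale; without them a 2%-of-range floor is used.
#' @return An object of class `"wedge_fit"`: `trajectory` (data frame
#'   `G`, `I0`), `upper` and `lower` line fits (or `NULL`), `e_i_hat`,
#'   `se_e_i`, `e_e_hat`, `se_e_e`, `e_i_ok`, `e_e_defaulted`,
#'   `default_reason`.
#' @export
fit_wedge <- function(G, V0, valid = NULL, config = sc_config(),
                      dG = NULL, dV0 = NULL) {
  if (is.null(valid)) valid <- is.finite(G) & is.finite(V0)
  Gv <- ifelse(valid, G, NA_real_)
  I0 <- compute_I0(Gv, ifelse(valid, V0, NA_real_))
  traj <- data.frame(G = Gv, I0 = I0)
  sigma_I0 <- if (!is.null(dG) && !is.null(dV0)) {
    sqrt((V0 * dG)^2 + (G * dV0)^2)
  }
  n_ok <- sum(is.finite(Gv) & is.finite(I0))

  upper <- lower <- NULL
  e_i_hat <- NA_real_; se_e_i <- NA_real_; e_i_ok <- FALSE
  e_e_hat <- config$e_e_default; se_e_e <- NA_real_
  e_e_defaulted <- TRUE; default_reason <- ""

  if (n_ok < config$boundary_min_bins ||
      stats::sd(Gv[is.finite(Gv)]) == 0) {
    default_reason <- "too few points"
  } else {
    upper <- boundary_search(Gv, I0, "upper",
                             min_len = config$boundary_min_bins,
                             min_r2 = config$boundary_min_r2,
                             sigma_I0 = sigma_I0)
    if (!is.null(upper)) {
      e_i_hat <- -upper$slope
      se_e_i <- upper$se_slope
      e_i_ok <- TRUE
    }
    lower <- boundary_search(Gv, I0, "lower",
                             min_len = config$boundary_min_bins,
                             min_r2 = config$boundary_min_r2,
                             sigma_I0 = sigma_I0)
    if (is.null(lower)) {
      default_reason <- "no acceptable lower boundary"
    } else {
      cand_ee <- -lower$slope
      if (cand_ee >= config$e_e_plausible[1] &&
          cand_ee <= config$e_e_plausible[2] &&
          (!e_i_ok || cand_ee > e_i_hat)) {
        e_e_hat <- cand_ee
        se_e_e <- lower$se_slope
        e_e_defaulted <- FALSE
      } else {
        default_reason <- sprintf(
          "lower-line slope implies Ee = %.1f mV outside [%g, %g]",
          cand_ee, config$e_e_plausible[1], config$e_e_plausible[2])
        lower <- NULL
      }
    }
  }
  structure(list(trajectory = traj, upper = upper, lower = lower,
                 e_i_hat = e_i_hat, se_e_i = se_e_i, e_i_ok = e_i_ok,
                 e_e_hat = e_e_hat, se_e_e = se_e_e,
                 e_e_defaulted = e_e_defaulted,
                 default_reason = default_reason),
            class = "wedge_fit")
}

#' @export
print.wedge_fit <- function(x, ...) {
  cat("<wedge_fit>\n")
  if (x$e_i_ok) {
    cat(sprintf("  Ei = %.1f mV (SE %.2f, %d boundary bins, R^2 %.3f)\n",
                x$e_i_hat, x$se_e_i, x$upper$n_bins, x$upper$r2))
  } else {
    cat("  Ei: estimation failed (no admissible upper boundary)\n")
  }
  if (x$e_e_defaulted) {
    cat(sprintf("  Ee = %.1f mV (default%s)\n", x$e_e_hat,
                if (nzchar(x$default_reason))
                  paste0("; ", x$default_reason) else ""))
  } else {
    cat(sprintf("  Ee = %.1f mV (SE %.2f, %d boundary bins, R^2 %.3f)\n",
                x$e_e_hat, x$se_e_e, x$lower$n_bins, x$lower$r2))
  }
  invisible(x)
}
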