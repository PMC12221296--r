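#' Split total conductance into inhibitory and excitatory components
#'
#' Given the reversal potentials, the total conductance and effective
#' resting potential determine the split uniquely:
#' `Gi = G (Ee - V0) / (Ee - Ei)` and `Ge = G (V0 - Ei) / (Ee - Ei)`, so
#' that `Gi + Ge = G` holds to round-off on every bin. A resting potential
#' outside `[Ei, Ee]` (possible with noisy fits or misspecified reversals)
#' produces a negative component; such values are retained and flagged,
#' never clipped, because clipping would hide reversal-potential
#' misspecification — the main artifact source, where part of the
#' inhibitory conductance gets mislabeled as excitatory.
#'
#' @param G total conductance per bin, nS.
#' @param V0 effective resting potential per bin, mV.
#' @param reversals a [reversal_pair()].
#' @param valid logical validity per bin (default: finite `G`).
#' @return A data frame `Gi`, `Ge` (nS), `neg_i`, `neg_e` (flags), `valid`.
#' @export
decompose_conductance <- function(G, V0, reversals, valid = NULL) {
  if (!inherits(reversals, "reversal_pair")) {
    reversals <- reversal_pair(reversals[[1]], reversals[[2]])
  }
  e_i <- reversals$e_i; e_e <- reversals$e_e
  den <- e_e - e_i
  if (den <= 0) stop("Ee must exceed Ei", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(G) & is.finite(V0)
  Gi <- ifelse(valid, G * (e_e - V0) / den, NA_real_)
  Ge <- ifelse(valid, G * (V0 - e_i) / den, NA_real_)
  data.frame(Gi = Gi, Ge = Ge,
             neg_i = valid & Gi < 0, neg_e = valid & Ge < 0,
             valid = valid)
}

#' Dynamic components and leak estimate
#'
#' Subtracts each component's minimum over the cycle (valid bins only):
#' `dGi = Gi - min Gi`, `dGe = Ge - min Ge`. The sum of the two minima is
#' the leak-conductance estimate (the static synaptic components cannot be
#' distinguished from leak). Ties in the minimizing phase are broken by the
#' first bin index, for determinism.
#'
#' @param Gi,Ge per-bin components, nS.
#' @param valid logical validity per bin.
#' @return A list `dGi`, `dGe` (nS, `>= 0` on valid bins), `g_leak_est`
#'   (nS), `argmin_i`, `argmin_e` (bin indices of the minima).
#' @export
dynamic_components <- function(Gi, Ge, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(Gi) & is.finite(Ge)
  if (!any(valid)) stop("all bins invalid", call. = FALSE)
  idx <- which(valid)
  argmin_i <- idx[which.min(Gi[idx])]
  argmin_e <- idx[which.min(Ge[idx])]
  min_i <- Gi[argmin_i]; min_e <- Ge[argmin_e]
  dGi <- ifelse(valid, Gi - min_i, NA_real_)
  dGe <- ifelse(valid, Ge - min_e, NA_real_)
  list(dGi = dGi, dGe = dGe, g_leak_est = min_i + min_e,
       argmin_i = argmin_i, argmin_e = argmin_e)
}

#' Standard error of a dynamic component
#'
#' The dynamic component is a difference of two measured conductances, the
#' bin's own and the one at the minimizing phase, so
#' `err(phi) = sqrt(dG(phi)^2 + dG(phi_m)^2)`; at the minimizing phase
#' itself this reduces to `sqrt(2) * dG(phi_m)`. The per-bin `dG` is used
#' for both components since the total conductance error bounds each
#' component's error from above.
#'
#' @param dG per-bin standard error of the total conductance, nS.
#' @param argmin bin index of the component's minimum.
#' @return Per-bin standard error of the dynamic component, nS.
#' @export
dynamic_errors <- function(dG, argmin) {
  if (is.na(dG[argmin])) stop("argmin must be a valid bin", call. = FALSE)
  sqrt(dG^2 + dG[argmin]^2)
}

#' One-tailed z-test for a dynamic component
#'
#' Tests, bin by bin, the null hypothesis that the dynamic component is
#' zero (no different from its minimum): `z = dG_dyn / err` with the
#' standard normal upper-tail p-value `p = 1 - Phi(z)`. Matching the
#' original procedure, no multiple-testing correction is applied by
#' default; Benjamini-Hochberg is available.
#'
#' @param dG_dyn per-bin dynamic component, nS.
#' @param err per-bin standard error, nS.
#' @param alpha significance level (strict `p < alpha`).
#' @param p_adjust `"none"` or `"BH"`.
#' @return A data frame `z`, `p`, `significant`.
#' @export
significance_test <- function(dG_dyn, err, alpha = 0.05,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  z <- dG_dyn / err
  zero_err <- is.finite(dG_dyn) & !is.na(err) & err == 0
  if (any(zero_err & dG_dyn > 0)) {
    warning("zero standard error with positive dynamic component; p set to 0")
    z[zero_err & dG_dyn > 0] <- Inf
  }
  z[zero_err & dG_dyn == 0] <- 0
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (p_adjust == "BH") {
    ok <- !is.na(p)
    p[ok] <- stats::p.adjust(p[ok], method = "BH")
  }
  data.frame(z = z, p = p, significant = !is.na(p) & p < alpha)
}

#' Full conductance profile from regression results
#'
#' Combines decomposition, dynamic components, error propagation and
#' significance testing into the per-bin conductance profile.
#'
#' @param G_tab output of [total_conductance()].
#' @param V0 per-bin effective resting potential, mV.
#' @param reversals a [reversal_pair()].
#' @param config an [sc_config()].
#' @return A data frame of class `"conductance_profile"` with attributes
#'   `g_leak_est`, `argmin_i`, `argmin_e`, `reversals`.
#' @export
conductance_profile <- function(G_tab, V0, reversals,
                                config = sc_config()) {
  dec <- decompose_conductance(G_tab$G, V0, reversals, valid = G_tab$valid)
  dyn <- dynamic_components(dec$Gi, dec$Ge, valid = dec$valid)
  err_i <- dynamic_errors(G_tab$dG, dyn$argmin_i)
  err_e <- dynamic_errors(G_tab$dG, dyn$argmin_e)
  sig_i <- significance_test(dyn$dGi, err_i, config$alpha, config$p_adjust)
  sig_e <- significance_test(dyn$dGe, err_e, config$alpha, config$p_adjust)
  out <- data.frame(
    phase_center = G_tab$phase_center, G = G_tab$G, dG = G_tab$dG,
    V0 = V0, Gi = dec$Gi, Ge = dec$Ge,
    dGi_dyn = dyn$dGi, dGe_dyn = dyn$dGe,
    err_i = err_i, err_e = err_e,
    z_i = sig_i$z, z_e = sig_e$z, p_i = sig_i$p, p_e = sig_e$p,
    sig_i = sig_i$significant, sig_e = sig_e$significant,
    neg_i = dec$neg_i, neg_e = dec$neg_e, valid = dec$valid)
  attr(out, "g_leak_est") <- dyn$g_leak_est
  attr(out, "argmin_i") <- dyn$argmin_i
  attr(out, "argmin_e") <- dyn$argmin_e
  attr(out, "reversals") <- reversals
  class(out) <- c("conductance_profile", "data.frame")
  out
}

#' Sensitivity of the decomposition to the reversal potentials
#'
#' Repeats the decomposition over a grid of reversal-potential pairs
#' (default: corners and midpoints of the configured ranges, a 3 x 3 grid)
#' and quantifies shape stability as the Pearson correlation between
#' max-normalized dynamic-component profiles across grid cells.
#'
#' @param G,V0 per-bin total conductance (nS) and resting potential (mV).
#' @param valid logical validity per bin.
#' @param e_e_range,e_i_range reversal ranges, mV.
#' @param grid number of grid points per axis, `c(n_e, n_i)`.
#' @return A list `grid` (data frame of pairs), `profiles` (list of
#'   [decompose_conductance()] + dynamic results), `cor_i`, `cor_e`
#'   (correlation matrices across grid cells).
#' @export
sensitivity_scan <- function(G, V0, valid = NULL,
                             e_e_range = c(-20, 0),
                             e_i_range = c(-110, -90),
                             grid = c(3L, 3L)) {
  stopifnot(e_e_range[1] <= e_e_range[2], e_i_range[1] <= e_i_range[2])
  ee <- if (grid[1] == 1L) mean(e_e_range) else
    seq(e_e_range[1], e_e_range[2], length.out = grid[1])
  ei <- if (grid[2] == 1L) mean(e_i_range) else
    seq(e_i_range[1], e_i_range[2], length.out = grid[2])
  cells <- expand.grid(e_e = ee, e_i = ei)
  if (any(cells$e_e <= cells$e_i)) {
    stop("reversal grid contains Ee <= Ei", call. = FALSE)
  }
  profs <- lapply(seq_len(nrow(cells)), function(k) {
    dec <- decompose_conductance(G, V0, reversal_pair(cells$e_i[k],
                                                      cells$e_e[k]),
                                 valid = valid)
    dyn <- dynamic_components(dec$Gi, dec$Ge, valid = dec$valid)
    list(e_i = cells$e_i[k], e_e = cells$e_e[k],
         dGi = dyn$dGi, dGe = dyn$dGe)
  })
  norm_max <- function(x) {
    m <- max(x, na.rm = TRUE)
    if (m > 0) x / m else x
  }
  cormat <- function(field) {
    mat <- vapply(profs, function(p) norm_max(p[[field]]),
                  numeric(length(G)))
    ok <- stats::complete.cases(mat)
    stats::cor(mat[ok, , drop = FALSE])
  }
  list(grid = cells, profiles = profs,
       cor_i = cormat("dGi"), cor_e = cormat("dGe"))
}

#' Compare conductance profiles from two epochs
#'
#' Computes per-component Pearson correlations and relative RMS differences
#' of the dynamic components over jointly valid bins; used to check that
#' recording non-stationarity does not qualitatively change the
#' reconstruction.
#'
#' @param a,b two [conductance_profile()] data frames (equal bin count).
#' @return A list `r_i`, `r_e`, `rms_i`, `rms_e`, `n_bins`.
#' @export
compare_epochs <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("profiles have different bin counts",
                               call. = FALSE)
  both <- a$valid & b$valid
  if (!any(both)) stop("no overlapping valid bins", call. = FALSE)
  rel_rms <- function(x, y) {
    scale <- max(abs(c(x, y)))
    if (scale == 0) return(0)
    sqrt(mean((x - y)^2)) / scale
  }
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(r_i = safe_cor(a$dGi_dyn[both], b$dGi_dyn[both]),
       r_e = safe_cor(a$dGe_dyn[both], b$dGe_dyn[both]),
       rms_i = rel_rms(a$dGi_dyn[both], b$dGi_dyn[both]),
       rms_e = rel_rms(a$dGe_dyn[both], b$dGe_dyn[both]),
       n_bins = sum(both))
}
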