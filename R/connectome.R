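#' Respiratory phase windows
#'
#' Partitions the cycle into the three activity phases used for synaptic
#' input classification: inspiration `[0, r)`, post-inspiration
#' `[r, r + w)` and late expiration (E2) `[r + w, 1)`.
#'
#' @param r inspiratory fraction of the cycle.
#' @param w post-inspiratory fraction; default `(1 - r) / 2` (the real
#'   post-I/E2 split is physiological and not measured here).
#' @return A data frame of class `"phase_windows"`: `window`, `lo`, `hi`.
#' @export
phase_windows <- function(r = 0.33, w = (1 - r) / 2) {
  stopifnot(r > 0, w > 0, r + w < 1)
  out <- data.frame(window = c("I", "post_I", "E2"),
                    lo = c(0, r, r + w), hi = c(r, r + w, 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_windows", "data.frame")
  out
}

#' Classify significant synaptic inputs by phase window
#'
#' A window is labeled as receiving inhibition (resp. excitation) when at
#' least `min_frac` of its valid bins are "material": statistically
#' significant and at least `rel_min` of that component's cycle-wide peak.
#' A single significant bin is deliberately not enough to assert an
#' input, and the magnitude floor keeps
#' statistically-significant-but-minute components from asserting
#' connections the way a qualitative reading of the profiles never would
#' (small leakage from a slightly biased reversal potential is the known
#' mislabeling artifact, and single transition bins straddling an abrupt
#' conductance change are inflated by the membrane lag). Labels carry the
#' peak material dynamic conductance and its phase.
#'
#' @param profile a [conductance_profile()] with significance columns.
#' @param windows a [phase_windows()].
#' @param min_frac required fraction of significant bins (default 0.25).
#' @param rel_min required window peak relative to the component's
#'   cycle-wide peak (default 0.1).
#' @return A data frame, one row per window x sign: `window`, `sign`,
#'   `present`, `frac_significant`, `peak`, `peak_phase`.
#' @export
classify_inputs <- function(profile, windows = phase_windows(),
                            min_frac = 0.25, rel_min = 0.1) {
  rows <- list()
  for (k in seq_len(nrow(windows))) {
    inw <- profile$phase_center >= windows$lo[k] &
      profile$phase_center < windows$hi[k]
    for (sign in c("inhibitory", "excitatory")) {
      sig <- if (sign == "inhibitory") profile$sig_i else profile$sig_e
      dyn <- if (sign == "inhibitory") profile$dGi_dyn else profile$dGe_dyn
      use <- inw & profile$valid
      cyc_max <- suppressWarnings(max(dyn[profile$valid], na.rm = TRUE))
      material <- use & sig & !is.na(dyn) &
        dyn >= rel_min * max(cyc_max, 0)
      frac <- if (any(use)) sum(material) / sum(use) else 0
      present <- frac >= min_frac
      peak <- peak_phase <- NA_real_
      if (present) {
        j <- which(material)[which.max(dyn[material])]
        peak <- dyn[j]; peak_phase <- profile$phase_center[j]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window = windows$window[k], sign = sign, present = present,
        frac_significant = frac, peak = peak, peak_phase = peak_phase,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Infer functional-connectome motifs from classified inputs
#'
#' Applies the functional-connection rule: a connection from a source
#' population to the recorded neuron is asserted when the neuron carries a
#' statistically significant dynamic conductance component, of the
#' matching sign, in the phase range corresponding to the source
#' population's activity pattern. For every labeled window and sign, the
#' candidate sources are the phenotype templates whose activity overlaps
#' the window; each is scored by the product of its window overlap and the
#' Pearson correlation between its activity template and the dynamic
#' component over the union of the window and the template's support.
#' The best-scoring source is selected; candidates within `tie_tol` of the
#' best are reported as ties (including recurrent self-edges when the
#' target's own template matches). Windows with no overlapping template
#' are listed as unexplained. Transmitter identity is never asserted; only
#' the sign of the input is reported.
#'
#' Overlap is measured against the window's significant bins (where the
#' labeled component actually is), so a template active across the whole
#' window does not outscore one that matches exactly the sub-interval
#' carrying the input.
#'
#' @param profile a [conductance_profile()].
#' @param target the recorded neuron's phenotype name (for labeling and
#'   self-edge bookkeeping).
#' @param windows a [phase_windows()].
#' @param labels precomputed [classify_inputs()] output (optional).
#' @param templates activity templates from [phenotype_templates()]
#'   matching the profile's bin count.
#' @param min_frac window-labeling threshold, see [classify_inputs()].
#' @param tie_tol score difference below which candidates tie.
#' @param rel_min per-bin magnitude floor (relative to the component's
#'   cycle-wide peak) for the bins that define overlap, matching the
#'   window-labeling floor of [classify_inputs()].
#' @param support_min activity level above which a template counts as
#'   active.
#' @return An object of class `"motif_report"`: `target`, `edges` (data
#'   frame `source`, `sign`, `target`, `windows`, `score`), `labels`,
#'   `unexplained`.
#' @export
infer_motif <- function(profile, target = NA_character_,
                        windows = phase_windows(), labels = NULL,
                        templates = NULL, min_frac = 0.25,
                        tie_tol = 0.05, support_min = 0.05,
                        rel_min = 0.1) {
  n_bins <- nrow(profile)
  if (is.null(templates)) templates <- phenotype_templates(n_bins)
  if (is.null(labels)) {
    labels <- classify_inputs(profile, windows, min_frac, rel_min)
  }
  centers <- profile$phase_center
  support <- templates > support_min
  edge_rows <- list()
  unexplained <- character(0)
  for (k in which(labels$present)) {
    win <- labels$window[k]
    sgn <- labels$sign[k]
    wk <- which(windows$window == win)
    inw <- centers >= windows$lo[wk] & centers < windows$hi[wk]
    dyn <- if (sgn == "inhibitory") profile$dGi_dyn else profile$dGe_dyn
    sig <- if (sgn == "inhibitory") profile$sig_i else profile$sig_e
    cyc_max <- suppressWarnings(max(dyn[profile$valid], na.rm = TRUE))
    ref_bins <- inw & profile$valid & sig &
      !is.na(dyn) & dyn >= rel_min * max(cyc_max, 0)
    if (!any(ref_bins)) ref_bins <- inw
    overlap <- colSums(support & ref_bins) / sum(ref_bins)
    cand <- which(overlap > 0)
    if (!length(cand)) {
      unexplained <- c(unexplained, paste(win, sgn))
      next
    }
    scores <- vapply(cand, function(j) {
      region <- inw | support[, j]
      x <- templates[region, j]; y <- dyn[region]
      ok <- is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      overlap[j] * stats::cor(x[ok], y[ok])
    }, 0)
    if (all(is.na(scores))) {
      unexplained <- c(unexplained, paste(win, sgn))
      next
    }
    best <- max(scores, na.rm = TRUE)
    winners <- cand[!is.na(scores) & scores >= best - tie_tol]
    for (j in winners) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        source = colnames(templates)[j], sign = sgn, target = target,
        windows = win, score = scores[match(j, cand)],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_rows)) {
    all_edges <- do.call(rbind, edge_rows)
    # merge duplicate source/sign pairs found in several windows
    key <- paste(all_edges$source, all_edges$sign)
    merged <- lapply(split(all_edges, key), function(d) {
      data.frame(source = d$source[1], sign = d$sign[1],
                 target = d$target[1],
                 windows = paste(sort(unique(d$windows)), collapse = "+"),
                 score = max(d$score), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
    out[order(-out$score), , drop = FALSE]
  } else {
    data.frame(source = character(0), sign = character(0),
               target = character(0), windows = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(target = target, edges = edges, labels = labels,
                 unexplained = unexplained),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> target: %s\n", x$target))
  if (nrow(x$edges)) {
    for (k in seq_len(nrow(x$edges))) {
      e <- x$edges[k, ]
      arrow <- if (e$sign == "inhibitory") "-|" else "->"
      cat(sprintf("  %s %s %s  [%s, score %.2f]\n", e$source, arrow,
                  e$target, e$windows, e$score))
    }
  } else {
    cat("  no edges\n")
  }
  if (length(x$unexplained)) {
    cat("  unexplained:", paste(x$unexplained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a motif report as an edge list
#'
#' @param report a [infer_motif()] result.
#' @param path destination path for a tab-delimited edge list.
#' @return `path`, invisibly.
#' @export
write_motif_edges <- function(report, path) {
  utils::write.table(report$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
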