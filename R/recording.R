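#' Intracellular recording container
#'
#' Holds the time-aligned traces the reconstruction operates on: membrane
#' potential, injected (or clamp) current, and the reference nerve signal,
#' all on one uniform time grid.
#'
#' Canonical units: time in s, membrane potential in mV, current in pA,
#' reference signal in arbitrary units. In current-clamp mode `i_inj` is the
#' controlled stepwise injected current and `vm` the measured potential; in
#' voltage-clamp mode `vm` is the controlled command potential and `i_inj`
#' the measured clamp current.
#'
#' @param time sample times, s; strictly increasing uniform grid.
#' @param vm membrane (or command) potential, mV.
#' @param i_inj injected (or clamp) current, pA.
#' @param ref reference nerve signal, arbitrary units.
#' @param sample_rate sampling rate, Hz; must match the grid step.
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param metadata free-form named list carried through to output headers.
#' @return An object of class `"sc_recording"`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- recording(t, vm = rep(-60, length(t)), i_inj = rep(0, length(t)),
#'                  ref = rep(0, length(t)), sample_rate = 100)
recording <- function(time, vm, i_inj, ref, sample_rate,
                      clamp_mode = c("current_clamp", "voltage_clamp"),
                      metadata = list()) {
  clamp_mode <- match.arg(clamp_mode)
  rec <- structure(
    list(time = as.numeric(time), vm = as.numeric(vm),
         i_inj = as.numeric(i_inj), ref = as.numeric(ref),
         sample_rate = as.numeric(sample_rate), clamp_mode = clamp_mode,
         metadata = metadata),
    class = "sc_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  n <- length(rec$time)
  if (n < 2L) stop("recording must contain at least 2 samples", call. = FALSE)
  for (ch in c("vm", "i_inj", "ref")) {
    if (length(rec[[ch]]) != n) {
      stop(sprintf("channel '%s' length (%d) differs from time grid (%d)",
                   ch, length(rec[[ch]]), n), call. = FALSE)
    }
  }
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0) {
    stop("sample_rate must be a positive number", call. = FALSE)
  }
  dt <- diff(rec$time)
  step <- 1 / rec$sample_rate
  if (any(dt <= 0) || max(abs(dt - step)) > 1e-9 * max(step, 1)) {
    stop("time must be strictly increasing with constant step 1/sample_rate",
         call. = FALSE)
  }
  rec
}

#' @export
print.sc_recording <- function(x, ...) {
  cat(sprintf(
    "<sc_recording> %d samples @ %g Hz (%.2f s), %s\n",
    length(x$time), x$sample_rate, diff(range(x$time)),
    gsub("_", " ", x$clamp_mode)))
  cat(sprintf("  vm    [%.1f, %.1f] mV\n", min(x$vm), max(x$vm)))
  cat(sprintf("  i_inj [%.1f, %.1f] pA\n", min(x$i_inj), max(x$i_inj)))
  invisible(x)
}

#' Extract a time slice of a recording
#'
#' @param rec an [recording()] object.
#' @param t_start,t_end inclusive-start, exclusive-end time window, s.
#' @return A new `sc_recording` covering `[t_start, t_end)`.
#' @export
subset_recording <- function(rec, t_start = -Inf, t_end = Inf) {
  keep <- rec$time >= t_start & rec$time < t_end
  if (sum(keep) < 2L) stop("time window selects fewer than 2 samples",
                           call. = FALSE)
  recording(rec$time[keep], rec$vm[keep], rec$i_inj[keep], rec$ref[keep],
            rec$sample_rate, rec$clamp_mode, rec$metadata)
}

#' Read a recording from the delimited-text exchange format
#'
#' The exchange format is a comma-separated table with columns
#' `time, vm, i_inj, ref` preceded by comment lines of the form
#' `# sample_rate_hz=...` and `# clamp_mode=...`.
#'
#' @param path file path.
#' @param format file format; only `"csv"` is supported.
#' @return An `sc_recording`.
#' @export
read_recording <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L)
  header <- grep("^#", lines, value = TRUE)
  get_attr <- function(key) {
    hit <- grep(paste0(key, "="), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0(".*", key, "=\\s*([^;[:space:]]+).*"), "\\1", hit[1])
  }
  rate <- suppressWarnings(as.numeric(get_attr("sample_rate_hz")))
  if (!is.finite(rate)) {
    stop("format error: missing '# sample_rate_hz=' header", call. = FALSE)
  }
  mode <- get_attr("clamp_mode")
  if (is.na(mode)) mode <- "current_clamp"
  dat <- utils::read.csv(path, comment.char = "#")
  required <- c("time", "vm", "i_inj", "ref")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    stop("format error: missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recording(dat$time, dat$vm, dat$i_inj, dat$ref, rate, mode)
}

#' Write a recording in the delimited-text exchange format
#'
#' @param rec an `sc_recording`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%s; clamp_mode=%s",
                     format(rec$sample_rate, digits = 15), rec$clamp_mode),
             con)
  dat <- data.frame(time = rec$time, vm = rec$vm, i_inj = rec$i_inj,
                    ref = rec$ref)
  utils::write.table(format(dat, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
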