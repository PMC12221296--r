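#' Write a conductance profile as delimited text
#'
#' One row per phase bin with columns `phase_center, G, dG, V0, Gi, Ge,
#' dGi_dyn, dGe_dyn, err_i, err_e, z_i, z_e, p_i, p_e, valid`. Invalid
#' bins are emitted with the `NA` missing-value sentinel and
#' `valid = FALSE`, never dropped or interpolated. Header comment lines
#' record the reversal potentials, the leak estimate and the fully
#' serialized configuration (with its hash), so every output is
#' self-describing.
#'
#' @param profile a [conductance_profile()] or [syncond()] fit.
#' @param path destination file path.
#' @param config the [sc_config()] to serialize into the header
#'   (taken from the fit when `profile` is a `syncond` object).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, config = sc_config()) {
  if (inherits(profile, "syncond")) {
    config <- profile$config
    profile <- profile$profile
  }
  rev <- attr(profile, "reversals")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# e_i_mv=%s", format(rev$e_i, digits = 17)),
    sprintf("# e_e_mv=%s", format(rev$e_e, digits = 17)),
    sprintf("# g_leak_est_ns=%s",
            format(attr(profile, "g_leak_est"), digits = 17)),
    config_header_lines(config)), con)
  cols <- c("phase_center", "G", "dG", "V0", "Gi", "Ge", "dGi_dyn",
            "dGe_dyn", "err_i", "err_e", "z_i", "z_e", "p_i", "p_e",
            "valid")
  dat <- as.data.frame(profile)[, cols]
  num <- vapply(dat, is.numeric, TRUE)
  dat[num] <- lapply(dat[num], function(x) format(x, digits = 17,
                                                  trim = TRUE))
  utils::write.table(dat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a conductance profile written by [write_profile()]
#'
#' @param path file path.
#' @return A data frame of class `"conductance_profile"` with the
#'   reversal potentials and leak estimate restored as attributes.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- grep("^#", readLines(path, n = 60L), value = TRUE)
  get_num <- function(key) {
    hit <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, "="), "", hit[1]))
  }
  out <- utils::read.delim(path, comment.char = "#")
  out$valid <- as.logical(out$valid)
  attr(out, "g_leak_est") <- get_num("g_leak_est_ns")
  e_i <- get_num("e_i_mv"); e_e <- get_num("e_e_mv")
  if (is.finite(e_i) && is.finite(e_e)) {
    attr(out, "reversals") <- reversal_pair(e_i, e_e)
  }
  class(out) <- c("conductance_profile", "data.frame")
  out
}
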