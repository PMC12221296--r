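# Shared simulation fixtures, built once per test run. All fixtures are
# generated in code (no stored data) and cached because the full
# simulate-and-fit cycle costs about two seconds each.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

true_reversals <- function() reversal_pair(-90, -10)

std_noiseless <- function() {
  cached("std0", make_standard_fixture(seed = 1L, noise_sd = 0))
}

fit_noiseless <- function() {
  cached("fit0", syncond(std_noiseless()$recording,
                         reversals = true_reversals()))
}

std_noisy <- function() {
  cached("std05", make_standard_fixture(seed = 42L, noise_sd = 0.5))
}

fit_noisy <- function() {
  cached("fit05", syncond(std_noisy()$recording,
                          reversals = true_reversals()))
}

# same fit but with pipeline-estimated reversals (wedge path)
fit_noisy_wedge <- function() {
  cached("fit05w", syncond(std_noisy()$recording))
}

std_noisy_vc <- function() {
  cached("std05vc", make_standard_fixture(seed = 42L,
                                          mode = "voltage_clamp",
                                          noise_sd = 0.5))
}

fit_noisy_vc <- function() {
  cached("fit05vc", syncond(std_noisy_vc()$recording,
                            reversals = true_reversals()))
}

# dynamic-component truth on the bin grid
truth_dyn <- function(sim) {
  list(dgi = sim$truth$gi_bins - min(sim$truth$gi_bins),
       dge = sim$truth$ge_bins - min(sim$truth$ge_bins))
}

recovery_rmse <- function(fit, sim) {
  tr <- truth_dyn(sim)
  v <- fit$profile$valid
  list(
    rel_i = sqrt(mean((fit$profile$dGi_dyn[v] - tr$dgi[v])^2)) /
      max(tr$dgi),
    rel_e = sqrt(mean((fit$profile$dGe_dyn[v] - tr$dge[v])^2)) /
      max(tr$dge))
}

# motif bookkeeping against a fixture's ground-truth source populations
motif_outcome <- function(fit, sim) {
  truth <- sim$truth$edges
  got <- fit$motifs$edges
  recovered <- all(apply(truth, 1, function(e)
    any(got$source == e[["source"]] & got$sign == e[["sign"]])))
  wrong_sign <- any(vapply(seq_len(nrow(got)), function(k) {
    m <- truth$source == got$source[k]
    any(m) && !any(truth$sign[m] == got$sign[k])
  }, logical(1)))
  list(recovered = recovered, wrong_sign = wrong_sign)
}
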