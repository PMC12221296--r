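test_that("the decomposition solves the reversal-potential system", {
  d <- decompose_conductance(10, -50, reversal_pair(-90, -10))
  expect_equal(d$Gi, 5)
  expect_equal(d$Ge, 5)

  # wedge boundaries: V0 at a reversal puts everything in one component
  expect_equal(decompose_conductance(10, -90, reversal_pair(-90, -10))$Gi,
               10)
  expect_equal(decompose_conductance(10, -10, reversal_pair(-90, -10))$Ge,
               10)

  expect_error(reversal_pair(-50, -50), "exceed")

  # negative components are retained and flagged, not clipped
  d2 <- decompose_conductance(10, -95, reversal_pair(-90, -10))
  expect_lt(d2$Ge, 0)
  expect_true(d2$neg_e)
  expect_false(d2$neg_i)
})

test_that("decomposition is exactly linear in the total conductance", {
  set.seed(7)
  G <- runif(50, 8, 20)
  V0 <- runif(50, -85, -40)
  d1 <- decompose_conductance(G, V0, reversal_pair(-90, -10))
  d3 <- decompose_conductance(3 * G, V0, reversal_pair(-90, -10))
  expect_equal(d3$Gi, 3 * d1$Gi)
  expect_equal(d3$Ge, 3 * d1$Ge)
  dy1 <- dynamic_components(d1$Gi, d1$Ge)
  dy3 <- dynamic_components(d3$Gi, d3$Ge)
  expect_equal(dy3$dGi, 3 * dy1$dGi)
  expect_equal(dy3$g_leak_est, 3 * dy1$g_leak_est)
})

test_that("dynamic components subtract minima over valid bins only", {
  Gi <- c(2, 2, 2, 2)
  Ge <- c(1, 3, 5, 1)
  dyn <- dynamic_components(Gi, Ge)
  expect_equal(dyn$dGi, rep(0, 4))
  expect_equal(dyn$g_leak_est, 3)        # min Gi + min Ge
  expect_equal(dyn$argmin_i, 1L)         # first bin on ties
  expect_equal(dyn$argmin_e, 1L)

  # invalid bins carry no information about the minima
  dyn2 <- dynamic_components(c(0.1, 2, 3), c(0.1, 1, 2),
                             valid = c(FALSE, TRUE, TRUE))
  expect_equal(dyn2$g_leak_est, 3)
  expect_error(dynamic_components(1, 1, valid = FALSE), "invalid")
})

test_that("leak estimate recovers the simulator ground truth", {
  # waveforms touch zero, so min Gi + min Ge is the leak plus nothing
  gi <- conductance_template("bell", 0.33, 0.88, peak = 6, baseline = 0)
  ge <- conductance_template("bell", 0.88, 1.32, peak = 3, baseline = 0)
  proto <- clamp_protocol("current_clamp",
                          levels = c(-100, -200, -300, -400, -500),
                          cycles_per_level = 6L)
  sim <- simulate_neuron(neuron_params(g_leak = 5, C = 50), gi, ge, proto,
                         noise_sd = 0.5, seed = 8L)
  fit <- syncond(sim$recording, reversals = true_reversals())
  expect_lt(abs(fit$g_leak_est - 5) / 5, 0.05)
})

test_that("dynamic-component errors follow the two-bin propagation rule", {
  expect_equal(dynamic_errors(c(0.3, 0.4), argmin = 2L)[1], 0.5)
  dG <- rep(0.7, 10)
  expect_equal(dynamic_errors(dG, 3L), rep(0.7 * sqrt(2), 10))
  expect_equal(dynamic_errors(c(0.3, 0), 2L)[1], 0.3)
  expect_error(dynamic_errors(c(0.3, NA), 2L), "valid bin")
})

test_that("the one-tailed z-test matches the normal upper tail", {
  s0 <- significance_test(0, 0.4)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 0.5)
  expect_false(s0$significant)

  s1 <- significance_test(1.0, 0.4)
  expect_equal(s1$z, 2.5)
  expect_equal(s1$p, pnorm(2.5, lower.tail = FALSE))
  expect_equal(s1$p, 0.0062, tolerance = 1e-2)
  expect_true(s1$significant)

  # exact boundary: p = alpha is not significant under strict <
  zb <- qnorm(0.95)
  sb <- significance_test(zb * 0.4, 0.4)
  expect_equal(sb$p, 0.05)
  expect_false(sb$significant)

  expect_warning(out <- significance_test(1, 0), "zero standard error")
  expect_equal(out$p, 0)

  # BH correction is monotone and never creates significance
  set.seed(3)
  dg <- abs(rnorm(50)); err <- rep(1, 50)
  raw <- significance_test(dg, err)
  bh <- significance_test(dg, err, p_adjust = "BH")
  expect_true(all(bh$p >= raw$p))
})

test_that("conservation holds bin-wise to round-off on all fixtures", {
  for (fit in list(fit_noisy(), fit_noisy_vc(), fit_noiseless())) {
    p <- fit$profile
    v <- p$valid
    expect_lt(max(abs(p$Gi[v] + p$Ge[v] - p$G[v]) / p$G[v]), 1e-9)
    lhs <- attr(p, "g_leak_est") + p$dGi_dyn[v] + p$dGe_dyn[v]
    expect_lt(max(abs(lhs - p$G[v]) / p$G[v]), 1e-9)
    expect_true(all(p$dGi_dyn[v] >= 0 & p$dGe_dyn[v] >= 0))
    expect_equal(min(p$dGi_dyn[v]), 0)
    expect_equal(min(p$dGe_dyn[v]), 0)
  }
})

test_that("recovery error grows monotonically with noise", {
  rmse <- vapply(c(0, 0.25, 0.5, 1.0), function(ns) {
    sim <- make_standard_fixture(seed = 21L, noise_sd = ns)
    fit <- syncond(sim$recording, reversals = true_reversals())
    r <- recovery_rmse(fit, sim)
    (r$rel_i + r$rel_e) / 2
  }, 0)
  expect_true(all(diff(rmse) > -1e-6))
  expect_lt(rmse[1], 0.01)
})

test_that("profile shape is stable across the reversal-potential grid", {
  fit <- fit_noisy_wedge()
  sc <- sensitivity_scan(fit$conductance$G, fit$regression$V0,
                         valid = fit$conductance$valid)
  expect_equal(dim(sc$cor_e), c(9, 9))
  expect_gte(min(sc$cor_e), 0.9)
  expect_gte(min(sc$cor_i), 0.9)

  # single-point grid degenerates to a trivial similarity matrix
  one <- sensitivity_scan(fit$conductance$G, fit$regression$V0,
                          valid = fit$conductance$valid,
                          grid = c(1L, 1L))
  expect_equal(dim(one$cor_e), c(1, 1))
  expect_equal(one$cor_e[1, 1], 1)

  expect_error(
    sensitivity_scan(fit$conductance$G, fit$regression$V0,
                     valid = fit$conductance$valid,
                     e_e_range = c(-100, -95), e_i_range = c(-90, -90)),
    "Ee <= Ei")
})

test_that("epoch comparison reports correlation and relative RMS", {
  a <- fit_noisy()$profile
  same <- compare_epochs(a, a)
  expect_equal(same$r_i, 1)
  expect_equal(same$rms_i, 0)

  b <- a
  b$dGi_dyn <- -b$dGi_dyn
  b$dGe_dyn <- -b$dGe_dyn
  neg <- compare_epochs(a, b)
  expect_equal(neg$r_i, -1)
  expect_equal(neg$r_e, -1)

  c2 <- a; c2$valid <- FALSE
  expect_error(compare_epochs(a, c2), "overlapping")
})
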