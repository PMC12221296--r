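test_that("the zero-current intercept is minus G times V0", {
  expect_equal(compute_I0(10, -50), 500)
  expect_equal(compute_I0(10, 0), 0)
  expect_equal(compute_I0(20, -50), 2 * compute_I0(10, -50))
})

test_that("boundary lines recover both reversal potentials (noiseless)", {
  fit <- fit_noiseless()
  w <- fit$wedge
  expect_true(w$e_i_ok)
  expect_lt(abs(w$e_i_hat - (-90)), 2)
  expect_false(w$e_e_defaulted)
  expect_lt(abs(w$e_e_hat - (-10)), 3)

  # upper intercept recovers -Ge0 (Ee - Ei) with the effective static
  # excitatory component (leak share folded in by the decomposition)
  ge0_eff <- min(fit$profile$Ge[fit$profile$valid])
  expect_lt(abs(w$upper$intercept - (-ge0_eff * 80)) / (ge0_eff * 80),
            0.15)
  gi0_eff <- min(fit$profile$Gi[fit$profile$valid])
  expect_lt(abs(w$lower$intercept - (gi0_eff * 80)) / (gi0_eff * 80),
            0.15)
})

test_that("inhibitory reversal recovery stays within 5 mV under noise", {
  errs <- vapply(1:20, function(s) {
    sim <- make_standard_fixture(seed = s, noise_sd = 0.5)
    fit <- syncond(sim$recording)
    fit$wedge$e_i_hat - (-90)
  }, 0)
  expect_lt(max(abs(errs)), 5)
})

test_that("degenerate trajectories fail or default gracefully", {
  # a single point repeated: no usable boundary
  w <- fit_wedge(rep(10, 20), rep(-60, 20))
  expect_false(w$e_i_ok)
  expect_true(w$e_e_defaulted)

  # three points: too few for any boundary fit
  w3 <- fit_wedge(c(10, 12, 14), c(-60, -65, -70))
  expect_false(w3$e_i_ok)
  expect_true(w3$e_e_defaulted)
  expect_match(w3$default_reason, "too few points")
})

test_that("absent zero-inhibition interval falls back to the default Ee", {
  # inhibition varies everywhere, so no pure-excitation segment exists
  gi <- conductance_template("bell", 0, 1, peak = 8, baseline = 1)
  ge <- conductance_template("bell", 0.9, 1.3, peak = 4, baseline = 0.5)
  proto <- clamp_protocol("current_clamp",
                          levels = c(-100, -200, -300, -400, -500),
                          cycles_per_level = 6L)
  sim <- simulate_neuron(neuron_params(), gi, ge, proto, noise_sd = 0.5,
                         seed = 12L)
  fit <- syncond(sim$recording)
  expect_true(fit$wedge$e_e_defaulted)
  expect_equal(fit$wedge$e_e_hat, -10)
  expect_equal(fit$reversals$e_e, -10)
})

test_that("trajectory points lie inside the true wedge", {
  sim <- std_noisy()
  fit <- fit_noisy()
  tr <- fit$wedge$trajectory
  v <- is.finite(tr$G)
  # true lines from the effective static components
  p <- fit$profile
  ge0 <- min(p$Ge[p$valid]); gi0 <- min(p$Gi[p$valid])
  upper <- 90 * tr$G[v] - ge0 * 80
  lower <- 10 * tr$G[v] + gi0 * 80
  margin <- 3 * sqrt(mean(p$err_i[p$valid]^2)) * 90  # error scale in pA
  inside <- tr$I0[v] <= upper + margin & tr$I0[v] >= lower - margin
  expect_gte(mean(inside), 0.95)
})

test_that("wedge-estimated Ei avoids the component-mislabeling artifact", {
  gi <- conductance_template("bell", 0.33, 0.88, peak = 12, baseline = 1)
  ge <- conductance_template("bell", 0.88, 1.32, peak = 4, baseline = 0.5)
  proto <- clamp_protocol("current_clamp",
                          levels = c(-100, -200, -300, -400, -500),
                          cycles_per_level = 10L)
  sim <- simulate_neuron(neuron_params(), gi, ge, proto, noise_sd = 0.5,
                         seed = 6L)
  with_wedge <- syncond(sim$recording)
  misspecified <- syncond(sim$recording,
                          reversals = reversal_pair(-75, -10))
  expect_lt(sum(with_wedge$profile$neg_e),
            sum(misspecified$profile$neg_e))
})
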