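test_that("simulated potentials settle at the algebraic steady state", {
  p <- neuron_params(C = 100, g_leak = 10, E_leak = -60)
  proto <- clamp_protocol("current_clamp", levels = 0,
                          cycles_per_level = 2L)
  sim <- simulate_neuron(p, gi = 5, ge = 0, proto, noise_sd = 0)
  expect_equal(tail(sim$recording$vm, 1), -70, tolerance = 0.01)

  proto2 <- clamp_protocol("current_clamp", levels = -100,
                           cycles_per_level = 2L)
  sim2 <- simulate_neuron(p, gi = 5, ge = 0, proto2, noise_sd = 0)
  expect_equal(tail(sim2$recording$vm, 1), -70 - 100 / 15,
               tolerance = 0.01)

  proto3 <- clamp_protocol("voltage_clamp", levels = -70,
                           cycles_per_level = 2L)
  sim3 <- simulate_neuron(p, gi = 5, ge = 0, proto3, noise_sd = 0)
  expect_equal(tail(sim3$recording$i_inj, 1), 0, tolerance = 1e-9)
})

test_that("with no input or current the membrane relaxes to E_leak", {
  p <- neuron_params()
  proto <- clamp_protocol("current_clamp", levels = 0,
                          cycles_per_level = 2L)
  sim <- simulate_neuron(p, gi = 0, ge = 0, proto, noise_sd = 0)
  expect_equal(tail(sim$recording$vm, 1), p$E_leak, tolerance = 1e-6)
})

test_that("steady state tracks slow waveforms to a tenth of a millivolt", {
  # long period so the waveform is glacial against tau_m
  p <- neuron_params()
  gi <- conductance_template("bell", 0.33, 0.88, peak = 8, baseline = 1)
  proto <- clamp_protocol("current_clamp", levels = -200,
                          cycles_per_level = 1L, period = 10,
                          sample_rate = 12500)
  sim <- simulate_neuron(p, gi, 0.5, proto, noise_sd = 0)
  t <- sim$recording$time
  phi <- (t %% 10) / 10
  g_i <- sim$truth$gi_fun(phi)
  g_tot <- 10 + g_i + 0.5
  v_inf <- (10 * (-65) + g_i * (-90) + 0.5 * (-10) - 200) / g_tot
  late <- t > 0.5  # skip the initial transient
  expect_lt(max(abs(sim$recording$vm[late] - v_inf[late])), 0.1)
})

test_that("an unstable Euler step is refused", {
  proto <- clamp_protocol("current_clamp", levels = 0,
                          cycles_per_level = 2L, sample_rate = 100)
  expect_error(simulate_neuron(neuron_params(), 5, 0, proto),
               "stability")
})

test_that("identical seeds give bit-identical recordings", {
  a <- make_standard_fixture(seed = 5L, noise_sd = 0.5)
  b <- make_standard_fixture(seed = 5L, noise_sd = 0.5)
  expect_identical(a$recording$vm, b$recording$vm)
  expect_identical(a$recording$ref, b$recording$ref)

  pa <- make_phenotype_fixture("post-I", seed = 3L)
  pb <- make_phenotype_fixture("post-I", seed = 3L)
  expect_identical(pa$recording$vm, pb$recording$vm)

  expect_error(make_phenotype_fixture("nonsense", seed = 1L))
})

test_that("phenotype fixtures realize the described input patterns", {
  # ramp-I cells: excitation rising through late expiration into
  # inspiration (the pre-I/I source pattern), inhibition through post-I
  # and E2, none during inspiration
  sim <- make_phenotype_fixture("ramp-I", seed = 1L, noise_sd = 0)
  gi <- sim$truth$gi_bins
  ge <- sim$truth$ge_bins
  centers <- sim$truth$bin_centers
  insp <- centers < 0.33
  late_e <- centers >= 0.84 & centers < 1
  expect_gt(cor(ge[late_e], centers[late_e]), 0.8)    # rising pre-I
  expect_true(all(ge[insp] > 3))                      # active through I
  expect_true(all(gi[centers >= 0.36 & centers < 0.6] > 1))   # post-I
  expect_true(all(gi[centers >= 0.8 & centers < 0.98] > 1))   # E2
  expect_true(all(gi[insp] <= 0.5 + 1e-9))

  # post-I cells: decrementing inspiratory inhibition, incrementing
  # late-expiratory inhibition
  sim2 <- make_phenotype_fixture("post-I", seed = 1L, noise_sd = 0)
  gi2 <- sim2$truth$gi_bins
  expect_lt(cor(gi2[insp], centers[insp]), -0.8)
  e2 <- centers >= 0.7
  expect_gt(cor(gi2[e2], centers[e2]), 0.8)
})

test_that("the null-bin harness exercises the real machinery", {
  nb <- simulate_null_bins(50, seed = 2L)
  expect_equal(nrow(nb), 50)
  expect_true(all(is.finite(nb$z)))
  # symmetric null: roughly half the dynamic components are negative
  expect_gt(mean(nb$dG_dyn < 0), 0.2)
})
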