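test_that("moving median removes lone spikes and passes slow waves", {
  vm <- rep(-60, 2000)
  vm[1000] <- 40
  out <- remove_spikes(vm, 1000, 0.1)
  expect_equal(out, rep(-60, 2000))

  t <- seq(0, 5, by = 1e-3)
  wave <- -60 + 5 * sin(2 * pi * t)
  filt <- remove_spikes(wave, 1000, 0.1)
  expect_lt(sqrt(mean((filt - wave)^2)) / sqrt(mean((wave + 60)^2)), 0.01)

  expect_error(remove_spikes(vm, 10, 0.1), "fewer than 3")
})

test_that("moving median is idempotent on spike-free inputs", {
  t <- seq(0, 5, by = 1e-3)
  for (x in list(-60 + 5 * sin(2 * pi * t), -70 + 2 * t)) {
    f1 <- remove_spikes(x, 1000, 0.1)
    f2 <- remove_spikes(f1, 1000, 0.1)
    expect_lt(max(abs(f2 - f1)), 1e-12)
  }
})

test_that("moving median suppresses simulated spikes riding a slow wave", {
  # spike transients painted on a simulated slow synaptic wave: the
  # filter must recover the wave itself
  gi <- conductance_template("bell", 0.33, 0.88, peak = 8, baseline = 1)
  proto <- clamp_protocol("current_clamp", levels = c(-100, -200),
                          cycles_per_level = 2L)
  clean <- simulate_neuron(neuron_params(), gi, 0.3, proto, noise_sd = 0)
  vm <- clean$recording$vm
  spike_len <- round(0.0015 * 12500)
  starts <- seq(2000, length(vm) - spike_len, by = 1000)  # 12.5 Hz firing
  spiky <- vm
  for (s0 in starts) spiky[s0:(s0 + spike_len - 1L)] <- 30
  filt <- remove_spikes(spiky, 12500, 0.1)
  expect_gte(stats::cor(filt, vm), 0.99)
  expect_lt(max(filt), -40)

  # the threshold-reset generator fires under depolarizing drive and the
  # filter removes those spikes too
  protod <- clamp_protocol("current_clamp", levels = c(250, 350),
                           cycles_per_level = 2L)
  dyn <- simulate_neuron(
    neuron_params(spike_threshold = -45, spike_reset = -65),
    gi, 0.3, protod, noise_sd = 0)
  expect_gt(max(dyn$recording$vm), 0)
  # interior samples only: the shrinking end windows deliberately leave
  # the trace edges unsmoothed
  fd <- remove_spikes(dyn$recording$vm, 12500, 0.1)
  interior <- seq(626, length(fd) - 625)
  expect_lt(max(fd[interior]), -40)
})

test_that("block-average downsampling preserves means and closed forms", {
  x <- rep(3.5, 12500)
  expect_equal(downsample_trace(x, 12500, 100), rep(3.5, 100))

  t <- seq(0, 2 - 1 / 12500, by = 1 / 12500)
  s <- sin(2 * pi * t)
  ds <- downsample_trace(s, 12500, 100)
  tc <- downsample_trace(t, 12500, 100)
  expect_lt(max(abs(ds - sin(2 * pi * tc) * sin(pi * 0.01) / (pi * 0.01))),
            1e-6)
  expect_lt(max(abs(ds - sin(2 * pi * tc))), 1e-3)
  expect_equal(mean(ds), mean(s))

  expect_error(downsample_trace(s, 12500, 300), "integer")
  expect_error(downsample_trace(s, 100, 200), "exceed")
})

test_that("rectify-integrate follows the first-order filter closed form", {
  expect_equal(rectify_integrate(rep(0, 100), 100, 0.05), rep(0, 100))

  rate <- 1000; tau <- 0.05
  x <- c(0, rep(1, 200))
  y <- rectify_integrate(x, rate, tau)
  k_tau <- round(tau * rate)
  expect_equal(y[k_tau + 1], 1 - exp(-1), tolerance = 2 / k_tau)
  expect_true(all(y >= 0))
  expect_error(rectify_integrate(x, 10, 0.05), "exceed")

  # burst train: smoothed envelope peaks inside each burst window
  t <- seq(0, 9 - 1e-3, by = 1e-3)
  env <- ifelse((t %% 3) < 1, 1, 0)
  yb <- rectify_integrate(env * abs(sin(200 * t)), 1000, 0.05)
  for (k in 0:2) {
    win <- t >= 3 * k & t < 3 * k + 1.2
    expect_true(t[win][which.max(yb[win])] > 3 * k &&
                  t[win][which.max(yb[win])] < 3 * k + 1.2)
  }
})

test_that("burst onsets are detected at the threshold crossing", {
  rate <- 1000
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  ph <- (t %% 3)
  tri <- pmax(0, 1 - abs(ph - 0.5) / 0.5)
  cs <- detect_burst_onsets(tri, rate, threshold_frac = 0.10)
  # rising edge crosses 0.1 at 0.05 s into each 3 s cycle
  expect_equal(cs$onsets, seq(0.05, by = 3, length.out = length(cs$onsets)),
               tolerance = 1e-3)
  expect_equal(unique(round(cs$periods, 6)), 3)
  expect_lt(cs$cv_period, 1e-10)

  expect_error(detect_burst_onsets(rep(1, 5000), rate, 0.1), "flat")
})

test_that("onset jitter propagates into the period CV as expected", {
  set.seed(2)
  onsets <- sort(cumsum(rep(3, 200)) + rnorm(200, sd = 0.05))
  cs <- cycle_set(onsets)
  expect_equal(cs$cv_period, sd(diff(onsets)) / mean(diff(onsets)),
               tolerance = 1e-12)
  # jitter sd 0.05 on onsets gives period sd ~ sqrt(2)*0.05
  expect_equal(cs$cv_period, sqrt(2) * 0.05 / 3, tolerance = 0.3)
})

test_that("onset count is recovered on noisy nerve signals", {
  set.seed(5)
  rate <- 1000
  t <- seq(0, 300 - 1 / rate, by = 1 / rate)
  phi <- (t %% 3) / 3
  env <- ifelse(phi >= 0.2 & phi < 0.53, 1, 0)
  ref <- env * abs(rnorm(length(t))) + 0.15 * rnorm(length(t))
  y <- rectify_integrate(ref, rate, 0.05)
  cs <- detect_burst_onsets(y, rate, 0.10)
  expect_equal(length(cs$onsets), 100)
})

test_that("phase is piecewise linear, resetting at onsets", {
  cs <- cycle_set(c(10, 13))
  expect_equal(compute_phase(11.5, cs)$phase, 0.5)
  expect_equal(compute_phase(10, cs)$phase, 0)

  cs2 <- cycle_set(c(0, 2, 5))
  ph <- compute_phase(3.5, cs2)
  expect_equal(ph$phase, 0.5)
  expect_equal(ph$cycle, 2)

  # samples outside the span are excluded; an empty overlap is an error
  out <- compute_phase(c(-1, 3.5, 6), cs2)
  expect_true(is.na(out$phase[1]) && is.na(out$phase[3]))
  expect_error(compute_phase(c(-1, 6), cs2), "no samples")

  # non-decreasing within a cycle, zero exactly at onsets
  t <- seq(0, 4.99, by = 0.01)
  p <- compute_phase(t, cs2)$phase
  within <- split(p, compute_phase(t, cs2)$cycle)
  for (seg in within) expect_true(all(diff(seg) > 0))
  expect_equal(p[t == 2], 0)
})

test_that("epoch quality control applies all three criteria", {
  cfg <- sc_config()
  # period CV from a plain cycle set
  cs <- cycle_set(cumsum(c(0, 3.0, 3.1, 2.9, 3.0, 3.0)))
  expect_equal(cs$cv_period, sd(c(3.0, 3.1, 2.9, 3.0, 3.0)) / 3,
               tolerance = 1e-6)
  expect_lt(cs$cv_period, cfg$cv_max)

  # 2 plateaus only -> min_steps failure
  two <- make_standard_fixture(seed = 1L, noise_sd = 0.5,
                               levels = c(-100, -300),
                               cycles_per_level = 6L)
  qc <- qc_epoch(two$recording, cfg)
  expect_false(qc$passed)
  expect_true(any(grepl("min_steps", qc$reasons)))

  # 4 steps x 6 cycles, stable baseline -> pass
  ok <- make_phenotype_fixture("ramp-I", seed = 2L, noise_sd = 0.5)
  qc2 <- qc_epoch(ok$recording, cfg)
  expect_true(qc2$passed)
  expect_equal(qc2$n_steps, 4)
  expect_false(qc2$drift_flag)
})
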