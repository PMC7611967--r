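test_that("generators are pure functions of their spec (seeded determinism)", {
  a <- genTailFamily(seed = 11); b <- genTailFamily(seed = 11)
  expect_identical(a$traces, b$traces)
  expect_false(identical(a$traces, genTailFamily(seed = 12)$traces))
  d1 <- genDualRecording(n_sweeps = 5, seed = 3)
  d2 <- genDualRecording(n_sweeps = 5, seed = 3)
  expect_identical(d1$soma_V_mV, d2$soma_V_mV)
  expect_identical(d1$bleb_I_pA, d2$bleb_I_pA)
  s1 <- genSpikeTrace(noise_sd = 0.02, seed = 9)
  s2 <- genSpikeTrace(noise_sd = 0.02, seed = 9)
  expect_identical(s1$x, s2$x)
  # the caller's RNG stream is not consumed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(genTailFamily(seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated metadata carries the ground truth needed downstream", {
  fam <- genTailFamily(seed = 2)
  expect_named(fam$ground_truth$boltzmann, c("Imax", "Imin", "v_half", "k"))
  expect_length(fam$ground_truth$amplitudes_pA,
                length(fam$prepulse_voltages_mV))
  rec <- genDualRecording(n_sweeps = 2, seed = 2)
  expect_equal(rec$ground_truth$latency_ms, 0.108)
  tr <- genSpikeTrace(seed = 2)
  expect_true(all(c("fwhm_ms", "sigma_ms", "centre_ms") %in%
                    names(tr$ground_truth)))
})

test_that("default tail family uses the standard voltage protocol", {
  fam <- genTailFamily(seed = 1)
  expect_equal(fam$prepulse_voltages_mV, seq(-56, -146, by = -10))
  expect_equal(fam$tail_voltage_mV, -136)
  expect_equal(fam$sampling_khz, 50)
})

test_that("noiseless tail families round-trip through the activation fit", {
  fam <- genTailFamily(noise_sd_pA = 0, seed = 1)
  fit <- fitActivation(fam)
  gt <- fam$ground_truth$boltzmann
  expect_equal(fit$Imax_pA, gt$Imax, tolerance = 1e-4)
  expect_equal(fit$Imin_pA, gt$Imin, tolerance = 1e-4)
  expect_equal(fit$v_half_mV, gt$v_half, tolerance = 1e-4)
  expect_equal(fit$k_per_mV, gt$k, tolerance = 1e-4)
})

test_that("noisy tail families give unbiased midpoint estimates", {
  vhs <- vapply(1:12, function(s) {
    fitActivation(genTailFamily(noise_sd_pA = 5, seed = s))$v_half_mV
  }, numeric(1))
  se <- sd(vhs) / sqrt(length(vhs))
  expect_lt(abs(mean(vhs) + 103.5), max(3 * se, 1))
})

test_that("dual-recording latency recovery is unbiased across the jitter grid", {
  for (jit in c(0, 0.02, 0.04)) {
    for (ns in c(10, 100)) {
      rec <- genDualRecording(latency_ms = 0.108, jitter_sd_ms = jit,
                              n_sweeps = ns, seed = 42)
      expect_lt(abs(measureLatency(rec) - 0.108), 0.02 + 1e-12,
                label = sprintf("latency bias (jitter %g, %d sweeps)",
                                jit, ns))
    }
  }
})

test_that("single noisy sweeps remain unbiased over many seeds", {
  errs <- vapply(1:60, function(s) {
    rec <- genDualRecording(latency_ms = 0.108, jitter_sd_ms = 0.02,
                            n_sweeps = 1, seed = s)
    measureLatency(rec) - 0.108
  }, numeric(1))
  # wider spread than the 100-sweep case, but centred on the truth
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("events that would fall outside the sweep are rejected", {
  expect_error(genDualRecording(latency_ms = 15, sweep_ms = 16),
               "sweep window")
})

test_that("spike-trace generator produces exactly the requested width", {
  tr <- genSpikeTrace("gaussian", fwhm_ms = 0.30, noise_sd = 0, seed = 1)
  expect_equal(spikeWidthFwhm(tr$time_ms, tr$x), 0.30, tolerance = 0.005)
  # wider spike with 2% amplitude noise, recovered within 2% on average
  ws <- vapply(1:10, function(s) {
    tr2 <- genSpikeTrace("gaussian", fwhm_ms = 0.58, amplitude = 1,
                         noise_sd = 0.02, seed = s)
    spikeWidthFwhm(tr2$time_ms, tr2$x)
  }, numeric(1))
  expect_lt(abs(mean(ws) / 0.58 - 1), 0.02)
  # inverted (inward-current-like) events measure identically
  tr3 <- genSpikeTrace("gaussian", fwhm_ms = 0.30, amplitude = -1,
                       noise_sd = 0, seed = 1)
  expect_equal(spikeWidthFwhm(tr3$time_ms, tr3$x, polarity = "down"),
               spikeWidthFwhm(tr$time_ms, tr$x), tolerance = 1e-9)
})

test_that("biphasic traces carry a consistent dominant-lobe width", {
  tr <- genSpikeTrace("biphasic", fwhm_ms = 0.4, amplitude = 1,
                      noise_sd = 0, seed = 1, sampling_khz = 200)
  w <- spikeWidthFwhm(tr$time_ms, tr$x, polarity = "down")
  expect_equal(w, tr$ground_truth$fwhm_ms, tolerance = 0.02)
})
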