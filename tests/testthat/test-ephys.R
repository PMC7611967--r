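test_that("tail extrapolation recovers a clean exponential exactly", {
  tm <- seq(0, 400, by = 0.02)
  tr <- -100 * exp(-tm / 80)
  out <- extractTailAmplitude(tm, tr, tail_start_ms = 0)
  expect_false(out$flagged)
  expect_equal(out$amplitude_pA, -100, tolerance = 1e-6)
  expect_equal(out$tau_ms, 80, tolerance = 1e-6)
})

test_that("tail extrapolation is unbiased under Gaussian noise", {
  tm <- seq(0, 400, by = 0.02)
  amps <- vapply(1:30, function(s) {
    fam <- genTailFamily(boltzmann = c(Imax = -100, Imin = -100,
                                       v_half = -100, k = 0.1),
                         tau_ms = 80, prepulse_voltages_mV = -100,
                         noise_sd_pA = 5, seed = s)
    extractTailAmplitude(fam$time_ms, fam$traces[, 1], 0)$amplitude_pA
  }, numeric(1))
  expect_lt(abs(mean(amps) + 100), 3)
})

test_that("degenerate constant traces are flagged with a mean fallback", {
  tm <- seq(0, 100, by = 0.02)
  out <- extractTailAmplitude(tm, rep(-42, length(tm)), 0)
  expect_true(out$flagged)
  expect_equal(out$amplitude_pA, -42)
  expect_error(extractTailAmplitude(seq(0, 1, by = 0.02),
                                    rnorm(51), 0), "2 ms")
})

test_that("Boltzmann fit recovers generating parameters on exact data", {
  v <- seq(-56, -146, by = -10)
  I <- -20 + (-133 - -20) / (1 + exp(0.12 * (v - -103.5)))
  fit <- fitActivation(data.frame(voltage_mV = v, amplitude_pA = I))
  expect_equal(signif(fit$Imax_pA, 6), -20)
  expect_equal(signif(fit$Imin_pA, 6), -133)
  expect_equal(signif(fit$v_half_mV, 6), -103.5)
  expect_equal(signif(fit$k_per_mV, 6), 0.12)
  # midpoint identity: the fitted curve at V1/2 is the parameter midpoint
  p <- predict(fit, data.frame(voltage_mV = fit$v_half_mV))
  expect_equal(p, (fit$Imax_pA + fit$Imin_pA) / 2, tolerance = 1e-8)
})

test_that("maximal conductance follows from the tail driving force", {
  v <- seq(-56, -146, by = -10)
  I <- -20 + (-133 - -20) / (1 + exp(0.12 * (v - -103.5)))
  fit <- fitActivation(data.frame(voltage_mV = v, amplitude_pA = I),
                       vrev = -23, tail_voltage_mV = -136)
  # |Imax - Imin| = 113 pA over (Vrev - (-136)) = 113 mV -> magnitude 1.0 nS
  expect_equal(fit$gmax_nS, (fit$Imax_pA - fit$Imin_pA) / 113,
               tolerance = 1e-12)
  expect_equal(abs(fit$gmax_nS), 1, tolerance = 1e-6)
})

test_that("fit preconditions: enough voltages, midpoint coverage warning", {
  v <- c(-60, -80, -100, -120)
  I <- -20 + (-113) / (1 + exp(0.12 * (v + 103.5)))
  expect_error(fitActivation(data.frame(voltage_mV = v, amplitude_pA = I)),
               "at least 5")
  v2 <- seq(-56, -96, by = -10) # all above the midpoint
  I2 <- -20 + (-113) / (1 + exp(0.12 * (v2 + 103.5)))
  expect_warning(
    fitActivation(data.frame(voltage_mV = v2, amplitude_pA = I2)),
    "confidence")
})

test_that("zero-latency events measure as zero latency", {
  rec <- genDualRecording(latency_ms = 0, jitter_sd_ms = 0, n_sweeps = 3,
                          noise_sd_mV = 0, noise_sd_pA = 0, seed = 1)
  expect_lt(abs(measureLatency(rec)), 0.02 + 1e-12)
  # scaling both channels leaves the onsets, hence the latency, unchanged
  rec2 <- rec
  rec2$soma_V_mV <- rec$soma_V_mV * 2
  rec2$bleb_I_pA <- rec$bleb_I_pA * 5
  expect_equal(measureLatency(rec2), measureLatency(rec))
})

test_that("latency recovery from jittered noisy sweeps is sample-accurate", {
  rec <- genDualRecording(latency_ms = 0.108, jitter_sd_ms = 0.04,
                          n_sweeps = 100, seed = 1)
  expect_lt(abs(measureLatency(rec) - 0.108), 0.02 + 1e-12)
})

test_that("velocity conversion implements both initiation-site conventions", {
  # initiation at the soma edge: x_soma = 0 so both conventions agree
  v1 <- estimateVelocity(0.2, 0, 240, "mid_AIS_2x")
  v2 <- estimateVelocity(0.2, 0, 240, "end_AIS_3x")
  expect_equal(v1$v_m_per_s, 1.2)
  expect_equal(v2$v_m_per_s, 1.2)
  # mid-AIS with backward correction: (240 - 2*30)/0.15 um/ms = 1.2 m/s
  v3 <- estimateVelocity(0.15, 30, 240, "mid_AIS_2x")
  expect_equal(v3$v_m_per_s, 1.2)
  expect_identical(v3$multiplier, 2)
  # with x_soma > 0 the mid-AIS estimate always exceeds the AIS-end one
  v4 <- estimateVelocity(0.15, 30, 240, "end_AIS_3x")
  expect_gt(v3$v_m_per_s, v4$v_m_per_s)
  expect_error(estimateVelocity(0.15, 100, 240, "end_AIS_3x"),
               "end_AIS_3x")
  expect_error(estimateVelocity(0, 0, 240, "mid_AIS_2x"), "T must be > 0")
})

test_that("velocity is invariant under joint scaling of distance and time", {
  base <- estimateVelocity(0.15, 30, 240, "mid_AIS_2x")$v_m_per_s
  for (c_ in c(0.5, 2, 7)) {
    expect_equal(estimateVelocity(0.15 * c_, 30 * c_, 240 * c_,
                                  "mid_AIS_2x")$v_m_per_s,
                 base, tolerance = 1e-12)
  }
})

test_that("FWHM handles triangles, Gaussians and inverted peaks", {
  tm <- seq(0, 10, by = 0.002)
  tri <- pmax(0, 1 - abs(tm - 6) / 0.5) # base 1 ms triangle
  expect_equal(spikeWidthFwhm(tm, tri), 0.5, tolerance = 1e-3)
  gau <- exp(-(tm - 6)^2 / (2 * 0.2^2))
  expect_equal(spikeWidthFwhm(tm, gau), 2 * sqrt(2 * log(2)) * 0.2,
               tolerance = 0.01)
  expect_equal(spikeWidthFwhm(tm, -gau, polarity = "down"),
               spikeWidthFwhm(tm, gau), tolerance = 1e-9)
  # noise floor guard
  set.seed(7)
  expect_error(spikeWidthFwhm(tm, rnorm(length(tm), 0, 1), min_snr = 5),
               "baseline noise")
})
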