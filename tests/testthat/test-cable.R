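test_that("a passive model without stimulus sits exactly at its leak reversal", {
  m <- passiveChain(n = 8, leak = 0.02, e_leak = -70)
  ss <- steadyState(m)
  expect_equal(ss$V, rep(-70, 8), tolerance = 1e-9)
  sim <- simulateAxon(m, stimulus = NULL, dt = 0.05, t_end_ms = 5,
                      init = ss)
  expect_equal(max(abs(sim$V + 70)), 0, tolerance = 1e-9)
})

test_that("steady passive voltage profile matches the finite-cable solution", {
  # uniform unmyelinated cable, sealed ends, constant current at one end;
  # length ~ 1.5 length constants so the decay is well resolved
  g <- 0.005; d <- 1; n <- 40; Lc <- 10 # 40 x 10 um
  m <- passiveChain(n = n, length_um = Lc, diameter_um = d, leak = g,
                    e_leak = -70)
  sim <- simulateAxon(m, stimulusProtocol(1, 0, 400, 0.02), dt = 0.05,
                      t_end_ms = 400, record_stride = 800)
  V <- sim$V[nrow(sim$V), ]
  x <- sim$position_um - sim$position_um[1]
  lam_um <- sqrt((1 / (g * 100e-3 * pi * d * 1e-4)) /
                   (m$axial_resistivity / (pi * (d * 1e-4 / 2)^2))) * 1e4
  Ltot <- n * Lc - sim$position_um[1]
  pred <- cosh((Ltot - x) / lam_um) / cosh(Ltot / lam_um)
  obs <- (V + 70) / (V[1] + 70)
  expect_lt(max(abs(obs - pred) / pred[1]), 0.01)
})

test_that("the integrator satisfies discrete charge balance at every step", {
  # small node-paranode-internode-paranode-node chain, one segment per
  # compartment, passive; recompute both cable KCL residuals from the
  # recorded axonal and periaxonal trajectories
  n_ <- function() compartmentSpec("node", 1.5, 0.64, channel_densities = NULL,
                                   leak_density = 0.1, leak_reversal = -80)
  p_ <- function() compartmentSpec("paranode", 1.9, 0.73, n_wraps = 5,
                                   periaxonal_width_nm = 0.0123,
                                   channel_densities = NULL,
                                   leak_density = 0.001, leak_reversal = -80)
  i_ <- compartmentSpec("internode", 20, 0.73, n_wraps = 5,
                        periaxonal_width_nm = 15, channel_densities = NULL,
                        leak_density = 0.001, leak_reversal = -80)
  m <- axonModel(list(n_(), p_(), i_, p_(), n_()))
  sys <- assembleSystem(m, max_seg_um = 1000)
  expect_identical(sys$nseg, 5L)
  dt <- 0.01
  sim <- simulateAxon(m, stimulusProtocol(1, 0.1, 0.5, 0.2), dt = dt,
                      t_end_ms = 2, record_stride = 1, max_seg_um = 1000)
  V <- sim$V; U <- sim$V_peri; U[is.na(U)] <- 0
  tm <- sim$time
  inj_uA <- sim$injected_nA * 1e-3
  nsegs <- sys$nseg
  for (k in 2:length(tm)) {
    for (i in seq_len(nsegs)) {
      ax_in <- 0
      if (i > 1) ax_in <- ax_in + sys$gax_mS[i - 1] * (V[k, i - 1] - V[k, i])
      if (i < nsegs) ax_in <- ax_in + sys$gax_mS[i] * (V[k, i + 1] - V[k, i])
      stim <- if (i == 1) inj_uA[k - 1] else 0
      if (sys$is_myel[i]) {
        res1 <- sys$C_uF[i] * ((V[k, i] - U[k, i]) -
                                 (V[k - 1, i] - U[k - 1, i])) / dt +
          sys$gL_mS[i] * (V[k, i] - U[k, i] - sys$eL_mV[i]) - ax_in - stim
        peri_in <- 0
        if (i > 1 && sys$is_myel[i - 1])
          peri_in <- peri_in + sys$gperi_pair_mS[i - 1] *
            (U[k, i - 1] - U[k, i])
        if (i < nsegs && sys$is_myel[i + 1])
          peri_in <- peri_in + sys$gperi_pair_mS[i] * (U[k, i + 1] - U[k, i])
        peri_in <- peri_in - sys$gperi_ground_mS[i] * U[k, i]
        res2 <- sys$Cmy_uF[i] * (U[k, i] - U[k - 1, i]) / dt +
          sys$Gmy_mS[i] * U[k, i] -
          (sys$C_uF[i] * ((V[k, i] - U[k, i]) -
                            (V[k - 1, i] - U[k - 1, i])) / dt +
             sys$gL_mS[i] * (V[k, i] - U[k, i] - sys$eL_mV[i])) - peri_in
        expect_lt(abs(res2), 1e-10)
      } else {
        res1 <- sys$C_uF[i] * (V[k, i] - V[k - 1, i]) / dt +
          sys$gL_mS[i] * (V[k, i] - sys$eL_mV[i]) - ax_in - stim
      }
      expect_lt(abs(res1), 1e-10)
    }
  }
})

test_that("periaxonal states exist only under myelin", {
  m <- buildInfiniteAxon(n_nodes = 3)
  sys <- assembleSystem(m)
  expect_true(all(sys$is_myel[sys$kind %in% c("internode", "paranode")] == 1L))
  expect_true(all(sys$is_myel[sys$kind == "node"] == 0L))
  # periaxonal longitudinal coupling only between myelinated neighbours
  for (i in seq_len(sys$nseg - 1)) {
    if (sys$gperi_pair_mS[i] > 0)
      expect_true(sys$is_myel[i] == 1L && sys$is_myel[i + 1] == 1L)
  }
  # boundary segments of each sheath open to the bath
  expect_true(all(sys$gperi_ground_mS[sys$is_myel == 1L &
    c(sys$is_myel[-1] == 0L, TRUE)] > 0))
  sim <- simulateAxon(m, stimulusProtocol(1, 0.05, 0.1, 1), dt = 0.002,
                      t_end_ms = 1)
  expect_true(all(is.na(sim$V_peri[, sim$kind == "node"])))
  expect_true(all(is.finite(sim$V_peri[, sim$kind == "internode"])))
})

test_that("axial coupling conductances are reciprocal half-resistance sums", {
  m <- passiveChain(n = 3, length_um = 10, diameter_um = 2)
  sys <- assembleSystem(m, max_seg_um = 1000)
  r_half <- 70 * (10e-4 / 2) / (pi * (1e-4)^2) # Ohm
  expect_equal(sys$gax_mS[1], 1000 / (2 * r_half), tolerance = 1e-12)
})

test_that("simulation guards reject invalid protocols and report divergence", {
  m <- passiveChain(n = 3)
  expect_error(simulateAxon(m, stimulusProtocol(1, 0, 10, 1), t_end_ms = 5),
               "beyond the stimulus")
  expect_error(simulateAxon(m, dt = 0), "dt must be > 0")
  expect_error(stimulusProtocol(1, 0, -1, 1), "durations")
  expect_error(stimulusProtocol(1, 0, 1, Inf), "finite")
})

test_that("time grid is strictly increasing and voltages finite", {
  r <- infiniteRun(0)
  expect_true(all(diff(r$sim$time) > 0))
  expect_true(all(is.finite(r$sim$V)))
  # overshooting propagating spike under the shipped defaults
  expect_gt(max(r$sim$V[, 26]), 0)
})

test_that("long-format export is tidy and round-trips through the container", {
  m <- passiveChain(n = 3)
  sim <- simulateAxon(m, stimulusProtocol(1, 0.1, 0.2, 0.1), dt = 0.05,
                      t_end_ms = 1)
  df <- as.data.frame(sim)
  expect_identical(nrow(df), length(sim$time) * 3L)
  expect_named(df, c("compartment", "kind", "position_um", "time_ms",
                     "V_mV", "V_peri_mV"))
  tmp <- tempfile(fileext = ".rds"); csv <- tempfile(fileext = ".csv")
  saveSimulationResult(sim, tmp, csv = csv)
  back <- readSimulationResult(tmp)
  expect_equal(back$V, sim$V)
  expect_true(file.exists(csv))
  unlink(c(tmp, csv))
})
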