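# Seeded synthetic electrophysiology generators. Every generator is a pure
# function of its arguments: randomness comes from a private Mersenne-Twister
# stream seeded per call, and the caller's RNG state is left untouched. The
# ground-truth parameters are always echoed into the returned object so the
# expected analysis output can be recomputed from the data alone.

withPrivateSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Generate a voltage-clamp tail-current family with known ground truth
#'
#' For each pre-pulse voltage V the tail amplitude follows the Boltzmann
#' activation relation `A(V) = Imax + (Imin - Imax)/(1 + exp(k (V - V_half)))`
#' and the tail trace is a single exponential `A(V) exp(-t/tau)` plus
#' independent Gaussian noise, sampled at `sampling_khz`. Time zero is the end
#' of the pre-test pulse.
#'
#' @param boltzmann named vector/list with `Imax`, `Imin`, `v_half`, `k`
#'   (pA, pA, mV, 1/mV)
#' @param tau_ms tail time constant, ms
#' @param prepulse_voltages_mV pre-pulse grid (default -56 to -146 mV in
#'   -10 mV steps)
#' @param tail_voltage_mV common tail potential (default -136)
#' @param noise_sd_pA Gaussian noise SD, pA
#' @param duration_ms tail length, ms
#' @param sampling_khz sampling rate (default 50)
#' @param seed integer seed; identical seed and spec give bit-identical output
#' @return object of class `tail_current_family`: `time_ms`, `traces`
#'   (samples x voltages), `prepulse_voltages_mV`, `tail_voltage_mV`,
#'   `sampling_khz` and `ground_truth`
#' @export
genTailFamily <- function(boltzmann = c(Imax = -20, Imin = -133,
                                        v_half = -103.5, k = 0.12),
                          tau_ms = 80,
                          prepulse_voltages_mV = seq(-56, -146, by = -10),
                          tail_voltage_mV = -136,
                          noise_sd_pA = 5, duration_ms = 400,
                          sampling_khz = 50, seed = 1L) {
  b <- as.list(boltzmann)
  stopifnot(all(c("Imax", "Imin", "v_half", "k") %in% names(b)),
            tau_ms > 0, noise_sd_pA >= 0, sampling_khz > 0)
  vh <- b$v_half
  rng <- range(prepulse_voltages_mV)
  if (vh < rng[1] || vh > rng[2])
    warning("pre-pulse voltages do not span v_half; fits will be poorly ",
            "constrained")
  tm <- seq(0, duration_ms, by = 1 / sampling_khz)
  A <- b$Imax + (b$Imin - b$Imax) /
    (1 + exp(b$k * (prepulse_voltages_mV - vh)))
  traces <- withPrivateSeed(seed, {
    vapply(A, function(a) {
      a * exp(-tm / tau_ms) + stats::rnorm(length(tm), 0, noise_sd_pA)
    }, numeric(length(tm)))
  })
  structure(list(time_ms = tm, traces = traces,
                 prepulse_voltages_mV = prepulse_voltages_mV,
                 tail_voltage_mV = tail_voltage_mV,
                 sampling_khz = sampling_khz,
                 ground_truth = list(boltzmann = b, tau_ms = tau_ms,
                                     amplitudes_pA = A,
                                     noise_sd_pA = noise_sd_pA, seed = seed)),
            class = "tail_current_family")
}

# raised-cosine step from 0 to 1 over [0, rise]; identically 0 before onset,
# so the derivative-threshold onset coincides with the event time to within
# a sample
risingEvent <- function(t, onset, rise) {
  u <- (t - onset) / rise
  y <- numeric(length(t))
  up <- u > 0 & u < 1
  y[up] <- 0.5 * (1 - cos(pi * u[up]))
  y[u >= 1] <- 1
  y
}

# stylized action-potential waveform: sharp raised-cosine upstroke then
# exponential repolarization; returns mV relative to baseline
somaSpikeWave <- function(t, onset, amp = 100, rise = 0.3, decay = 1.2) {
  up <- risingEvent(t, onset, rise)
  dec <- ifelse(t > onset + rise, exp(-(t - onset - rise) / decay), 1)
  amp * up * dec
}

# closed-form time derivative of somaSpikeWave; identically zero before the
# onset, so the event's derivative-threshold onset is sample-exact (a
# discrete derivative would leak the onset one sample early)
somaSpikeWaveDeriv <- function(t, onset, amp = 100, rise = 0.3, decay = 1.2) {
  u <- (t - onset) / rise
  d <- numeric(length(t))
  on_rise <- u > 0 & u < 1
  d[on_rise] <- amp * 0.5 * (pi / rise) * sin(pi * u[on_rise])
  on_dec <- u >= 1
  d[on_dec] <- -amp * exp(-(t[on_dec] - onset - rise) / decay) / decay
  d
}

#' Generate a paired soma-voltage / bleb-current recording
#'
#' Each sweep contains one somatic action potential at a jittered time and a
#' bleb "action current" whose onset lags the somatic onset by the true
#' latency. The bleb event is modelled as a scaled negative time-derivative of
#' an action-potential-like waveform -- the simplest physically motivated
#' stand-in for a cell-attached capacitive current (a modelling choice, not a
#' claim about the recording pipette). Independent Gaussian noise is added per
#' channel. Both waveforms are identically zero before their onsets, so the
#' derivative-threshold onset convention of [measureLatency()] recovers the
#' ground-truth latency to within one sample.
#'
#' @param latency_ms true soma-to-bleb onset latency
#' @param jitter_sd_ms SD of the per-sweep somatic spike-time jitter
#' @param n_sweeps number of sweeps (the experimental procedure uses >= 100)
#' @param noise_sd_mV,noise_sd_pA channel noise RMS after band-limiting.
#'   Noise is generated white and low-pass filtered to `noise_filter_ms`
#'   (recordings are hardware-filtered well below the sampling rate; white
#'   noise at the full 50 kHz would make the derivative-threshold onset
#'   convention meaningless). Defaults emulate clean averaged-grade
#'   recordings.
#' @param noise_filter_ms boxcar width of the noise band-limiting filter
#' @param soma_amp_mV,bleb_amp_pA event amplitudes
#' @param sweep_ms sweep duration
#' @param event_ms nominal somatic event time within the sweep
#' @param sampling_khz sampling rate (default 50)
#' @param seed integer seed
#' @return object of class `dual_recording`: `soma_V_mV`, `bleb_I_pA`
#'   (samples x sweeps), `sampling_khz`, `time_ms`, `ground_truth`
#' @export
genDualRecording <- function(latency_ms = 0.108, jitter_sd_ms = 0.04,
                             n_sweeps = 100, noise_sd_mV = 0.02,
                             noise_sd_pA = 0.02, soma_amp_mV = 100,
                             bleb_amp_pA = 60, sweep_ms = 20, event_ms = 8,
                             noise_filter_ms = 0.25,
                             sampling_khz = 50, seed = 1L) {
  stopifnot(n_sweeps >= 1, latency_ms >= 0)
  dt <- 1 / sampling_khz
  tm <- seq(0, sweep_ms - dt, by = dt)
  guard <- 6 * jitter_sd_ms + latency_ms + 3
  if (event_ms + guard > sweep_ms || event_ms - 6 * jitter_sd_ms < 1)
    stop("event (latency + jitter) does not fit inside the sweep window")
  w_filt <- max(1L, as.integer(round(noise_filter_ms * sampling_khz)))
  bandNoise <- function(n, sd_post) {
    if (sd_post == 0) return(numeric(n))
    x <- stats::rnorm(n + 2 * w_filt, 0, sd_post * sqrt(w_filt))
    y <- as.numeric(stats::filter(x, rep(1 / w_filt, w_filt), sides = 2))
    y[(w_filt + 1):(w_filt + n)]
  }
  out <- withPrivateSeed(seed, {
    onsets <- event_ms + stats::rnorm(n_sweeps, 0, jitter_sd_ms)
    sv <- matrix(0, length(tm), n_sweeps)
    bi <- matrix(0, length(tm), n_sweeps)
    for (j in seq_len(n_sweeps)) {
      sv[, j] <- -80 + somaSpikeWave(tm, onsets[j], amp = soma_amp_mV) +
        bandNoise(length(tm), noise_sd_mV)
      # inward (negative) capacitive-like current: minus the closed-form
      # derivative of an AP-like waveform starting latency_ms after the
      # somatic onset
      dwdt <- somaSpikeWaveDeriv(tm, onsets[j] + latency_ms, amp = 1,
                                 rise = 0.25, decay = 0.5)
      bi[, j] <- -bleb_amp_pA * dwdt / max(abs(dwdt)) +
        bandNoise(length(tm), noise_sd_pA)
    }
    list(sv = sv, bi = bi, onsets = onsets)
  })
  structure(list(soma_V_mV = out$sv, bleb_I_pA = out$bi, time_ms = tm,
                 sampling_khz = sampling_khz, n_sweeps = n_sweeps,
                 ground_truth = list(latency_ms = latency_ms,
                                     jitter_sd_ms = jitter_sd_ms,
                                     onsets_ms = out$onsets,
                                     noise_sd_mV = noise_sd_mV,
                                     noise_sd_pA = noise_sd_pA, seed = seed)),
            class = "dual_recording")
}

#' Generate a single spike-like trace with known width
#'
#' `shape = "gaussian"` gives a Gaussian bump whose FWHM is exactly
#' `fwhm_ms`; `shape = "biphasic"` gives a derivative-of-Gaussian waveform
#' (an action-current-like up/down transient) whose dominant-lobe FWHM is
#' computed in closed form from the underlying sigma and echoed in the ground
#' truth.
#'
#' @param shape "gaussian" or "biphasic"
#' @param fwhm_ms requested full width at half-maximum of the dominant lobe
#' @param amplitude peak amplitude (negative for an inward-current-like event)
#' @param noise_sd Gaussian noise SD, same units as `amplitude`
#' @param duration_ms trace length (event centred)
#' @param sampling_khz sampling rate
#' @param seed integer seed
#' @return list of class `spike_trace`: `time_ms`, `x`, `ground_truth`
#' @export
genSpikeTrace <- function(shape = c("gaussian", "biphasic"), fwhm_ms = 0.3,
                          amplitude = 1, noise_sd = 0, duration_ms = 10,
                          sampling_khz = 50, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(fwhm_ms > 0)
  tm <- seq(0, duration_ms, by = 1 / sampling_khz)
  tc <- duration_ms * 0.6 # off-centre leaves a clean pre-spike baseline
  if (shape == "gaussian") {
    sigma <- fwhm_ms / (2 * sqrt(2 * log(2)))
    wave <- amplitude * exp(-(tm - tc)^2 / (2 * sigma^2))
    true_fwhm <- fwhm_ms
  } else {
    # g'(t) ~ -u exp(-u^2/2): lobe peak at u = 1; half-max of the dominant
    # lobe where u exp(-u^2/2) = exp(-1/2)/2, solved once for the unit shape
    f <- function(u) u * exp(-u^2 / 2) - 0.5 * exp(-0.5)
    uL <- stats::uniroot(f, c(1e-9, 1))$root
    uR <- stats::uniroot(f, c(1, 6))$root
    unit_fwhm <- uR - uL
    sigma <- fwhm_ms / unit_fwhm
    u <- (tm - tc) / sigma
    wave <- -amplitude * u * exp(-u^2 / 2) * exp(0.5) # peak |amplitude|
    true_fwhm <- fwhm_ms
  }
  x <- withPrivateSeed(seed, wave + stats::rnorm(length(tm), 0, noise_sd))
  structure(list(time_ms = tm, x = x,
                 ground_truth = list(shape = shape, fwhm_ms = true_fwhm,
                                     amplitude = amplitude, sigma_ms = sigma,
                                     centre_ms = tc, noise_sd = noise_sd,
                                     seed = seed)),
            class = "spike_trace")
}
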