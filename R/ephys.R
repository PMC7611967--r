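#' Extrapolated tail-current amplitude
#'
#' Fits a single exponential `A * exp(-(t - tail_start)/tau) + C` to the tail
#' current, skipping a capacitive-blanking interval after the voltage step,
#' and extrapolates back to the end of the pre-test pulse: the returned
#' amplitude is `A + C`, the fitted current at `tail_start`.
#'
#' A fitted time constant outside (0.5 ms, 5000 ms), or a failed fit (e.g. a
#' constant trace), is flagged; the flagged fallback amplitude is the mean of
#' the fitting window.
#'
#' @param time_ms,current_pA tail trace (time from a common sweep origin)
#' @param tail_start_ms time of the end of the pre-pulse / start of the tail
#' @param blank_ms capacitive-transient blanking interval after
#'   `tail_start_ms` excluded from the fit (default 1 ms)
#' @param window_ms fit window length after blanking (default: rest of trace)
#' @param tau_bounds_ms acceptable time-constant range, ms
#' @return list with `amplitude_pA` (extrapolated to `tail_start_ms`),
#'   `tau_ms`, `baseline_pA`, `flagged`, and the `fit` object (NULL when
#'   flagged)
#' @export
extractTailAmplitude <- function(time_ms, current_pA, tail_start_ms = 0,
                                 blank_ms = 1, window_ms = NULL,
                                 tau_bounds_ms = c(0.5, 5000)) {
  sel <- time_ms >= tail_start_ms + blank_ms
  if (!is.null(window_ms))
    sel <- sel & time_ms <= tail_start_ms + blank_ms + window_ms
  tt <- time_ms[sel] - tail_start_ms
  yy <- current_pA[sel]
  if (length(tt) < 10 || diff(range(tt)) < 2)
    stop("tail trace must contain at least 2 ms beyond the blanking interval")
  flagged_out <- function() list(amplitude_pA = mean(yy), tau_ms = NA_real_,
                                 baseline_pA = NA_real_, flagged = TRUE,
                                 fit = NULL)
  if (stats::sd(yy) < .Machine$double.eps^0.5 * (1 + abs(mean(yy))))
    return(flagged_out())
  # starting values: baseline from the trace end, tau from a log-linear fit
  C0 <- mean(yy[tt >= max(tt) * 0.8])
  A0 <- yy[1] - C0
  if (abs(A0) < .Machine$double.eps) A0 <- stats::sd(yy)
  dy <- (yy - C0) / A0
  ok <- dy > 1e-3 & tt <= max(tt) * 0.8
  tau0 <- if (sum(ok) > 2) {
    unname(-1 / stats::coef(stats::lm(log(dy[ok]) ~ tt[ok]))[2])
  } else diff(range(tt)) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(tt)) / 3
  fit <- tryCatch(
    minpack.lm::nls.lm(par = list(A = A0, tau = tau0, C = C0),
                       fn = function(p) yy - (p$A * exp(-tt / p$tau) + p$C),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(flagged_out())
  cf <- fit$par
  if (!is.finite(cf$tau) || cf$tau < tau_bounds_ms[1] ||
      cf$tau > tau_bounds_ms[2]) return(flagged_out())
  list(amplitude_pA = cf$A + cf$C, tau_ms = cf$tau, baseline_pA = cf$C,
       flagged = FALSE, fit = fit)
}

#' Boltzmann activation fit of a tail-current family
#'
#' Least-squares fit of the activation relation
#' `I = Imax + (Imin - Imax) / (1 + exp(k (V - V_half)))`
#' to extrapolated tail amplitudes versus pre-pulse voltage, with all four
#' parameters free. `Imax` is the tail amplitude after a large depolarizing
#' pre-pulse, `Imin` after a large hyperpolarizing one; `k > 0` with this
#' orientation (activation grows with hyperpolarization). The maximal
#' conductance follows as `Gmax = (Imax - Imin) / (Vrev - tail_voltage)`,
#' in nS for pA amplitudes and mV voltages.
#'
#' @param family a `tail_current_family` from [genTailFamily()], or a
#'   data.frame with columns `voltage_mV` and `amplitude_pA`
#' @param vrev Ih reversal potential, mV (default -23)
#' @param tail_voltage_mV voltage at which tails were measured (default -136;
#'   taken from the family when available)
#' @param ... passed to [extractTailAmplitude()] when raw traces are supplied
#' @return object of class `activation_fit`: list with `Imax_pA`, `Imin_pA`,
#'   `v_half_mV`, `k_per_mV`, `gmax_nS`, `vrev_mV`, `data`, `residuals`,
#'   `v_half_se` and the underlying `fit`
#' @export
fitActivation <- function(family, vrev = -23, tail_voltage_mV = -136, ...) {
  if (inherits(family, "tail_current_family")) {
    tail_voltage_mV <- family$tail_voltage_mV
    amps <- vapply(seq_along(family$prepulse_voltages_mV), function(j) {
      extractTailAmplitude(family$time_ms, family$traces[, j],
                           tail_start_ms = 0, ...)$amplitude_pA
    }, numeric(1))
    dat <- data.frame(voltage_mV = family$prepulse_voltages_mV,
                      amplitude_pA = amps)
  } else {
    dat <- as.data.frame(family)
    if (!all(c("voltage_mV", "amplitude_pA") %in% names(dat)))
      stop("need columns voltage_mV and amplitude_pA")
  }
  if (length(unique(dat$voltage_mV)) < 5)
    stop("need at least 5 distinct pre-pulse voltages")
  v <- dat$voltage_mV; I <- dat$amplitude_pA
  ord <- order(v)
  Imax0 <- I[ord][length(I)]  # most depolarized
  Imin0 <- I[ord][1]          # most hyperpolarized
  vh0 <- stats::approx(
    (I[ord] - Imax0) / (Imin0 - Imax0), v[ord], xout = 0.5, ties = mean)$y
  if (is.na(vh0)) vh0 <- stats::median(v)
  fit <- tryCatch(minpack.lm::nlsLM(
    I ~ Imax + (Imin - Imax) / (1 + exp(k * (v - vhalf))),
    start = list(Imax = Imax0, Imin = Imin0, vhalf = vh0, k = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the raw Levenberg-Marquardt optimizer, then restart nlsLM
    # at its solution so the returned object carries standard errors
    lm0 <- minpack.lm::nls.lm(
      par = list(Imax = Imax0, Imin = Imin0, vhalf = vh0, k = 0.1),
      fn = function(p) I - (p$Imax + (p$Imin - p$Imax) /
                              (1 + exp(p$k * (v - p$vhalf)))),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    fit <- minpack.lm::nlsLM(
      I ~ Imax + (Imin - Imax) / (1 + exp(k * (v - vhalf))),
      start = lm0$par,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  if (cf[["k"]] < 0) {
    # equivalent curve with Imax/Imin swapped; normalise orientation
    cf_new <- c(Imax = cf[["Imin"]], Imin = cf[["Imax"]],
                vhalf = cf[["vhalf"]], k = -cf[["k"]])
    cf <- cf_new
  }
  rng <- range(v)
  if (cf[["vhalf"]] < rng[1] || cf[["vhalf"]] > rng[2])
    warning("pre-pulse voltages do not span the fitted midpoint; ",
            "V_half has wide confidence")
  se <- tryCatch(summary(fit)$coefficients["vhalf", "Std. Error"],
                 error = function(e) NA_real_)
  gmax <- (cf[["Imax"]] - cf[["Imin"]]) / (vrev - tail_voltage_mV) # pA/mV = nS
  structure(list(Imax_pA = unname(cf[["Imax"]]),
                 Imin_pA = unname(cf[["Imin"]]),
                 v_half_mV = unname(cf[["vhalf"]]),
                 k_per_mV = unname(cf[["k"]]),
                 gmax_nS = unname(gmax), vrev_mV = vrev,
                 tail_voltage_mV = tail_voltage_mV,
                 data = dat, residuals = stats::residuals(fit),
                 v_half_se = se, fit = fit),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann activation fit: V1/2 = %.2f mV (SE %.2g), k = %.4f /mV\n",
    x$v_half_mV, x$v_half_se, x$k_per_mV))
  cat(sprintf("Imax = %.1f pA, Imin = %.1f pA, Gmax = %.3f nS (Vrev %g mV)\n",
              x$Imax_pA, x$Imin_pA, x$gmax_nS, x$vrev_mV))
  invisible(x)
}

#' Predicted tail amplitude from an activation fit
#' @param object an `activation_fit`
#' @param newdata data.frame with `voltage_mV` (default: the fitted data)
#' @param ... unused
#' @return predicted amplitudes, pA
#' @export
predict.activation_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage_mV else newdata$voltage_mV
  object$Imax_pA + (object$Imin_pA - object$Imax_pA) /
    (1 + exp(object$k_per_mV * (v - object$v_half_mV)))
}

centralDiff <- function(x, dt, k = 1L) {
  n <- length(x)
  d <- numeric(n)
  idx <- (k + 1):(n - k)
  d[idx] <- (x[idx + k] - x[idx - k]) / (2 * k * dt)
  d[seq_len(k)] <- d[k + 1]
  d[(n - k + 1):n] <- d[n - k]
  d
}

#' Soma-to-bleb latency from a dual recording
#'
#' Implements the derivative-alignment procedure: for every sweep the first
#' derivatives of the somatic voltage and the axonal (bleb) current are
#' formed; sweeps are time-shifted to align the peaks of the somatic
#' derivative; the aligned signals are averaged; then the somatic onset is the
#' last sample before the averaged dV/dt exceeds +1 mV/ms, and the bleb onset
#' the last sample before the averaged dI/dt falls below -0.5 pA/ms. The
#' threshold crossing is taken at the start of the contiguous suprathreshold
#' run that culminates in the spike's derivative extremum, so isolated noise
#' crossings far from the event are ignored. The latency is onset(bleb)
#' minus onset(soma).
#'
#' @param rec a `dual_recording` (see [genDualRecording()]): list with
#'   `soma_V_mV` and `bleb_I_pA` matrices (samples x sweeps) and
#'   `sampling_khz`
#' @param soma_threshold somatic derivative onset threshold, mV/ms (+1)
#' @param bleb_threshold bleb derivative onset threshold, pA/ms (-0.5)
#' @param deriv_base_ms full base of the central difference (default 0.2 ms,
#'   i.e. samples +/-0.1 ms apart at 50 kHz). The thresholds sit at ~0.1% of
#'   the events' peak derivatives, so the slope must be estimated over a base
#'   matched to the recording bandwidth rather than single adjacent samples.
#'   Identical for both channels, so any onset shift it introduces cancels
#'   in the latency difference.
#' @return latency, ms
#' @export
measureLatency <- function(rec, soma_threshold = 1, bleb_threshold = -0.5,
                           deriv_base_ms = 0.2) {
  sv <- rec$soma_V_mV; bi <- rec$bleb_I_pA
  if (is.null(dim(sv))) sv <- matrix(sv, ncol = 1)
  if (is.null(dim(bi))) bi <- matrix(bi, ncol = 1)
  stopifnot(nrow(sv) == nrow(bi), ncol(sv) == ncol(bi))
  dt <- 1 / rec$sampling_khz # ms per sample
  k <- max(1L, as.integer(round(deriv_base_ms * rec$sampling_khz / 2)))
  nsw <- ncol(sv); nsamp <- nrow(sv)
  dV <- apply(sv, 2, centralDiff, dt = dt, k = k)
  dI <- apply(bi, 2, centralDiff, dt = dt, k = k)
  peaks <- apply(dV, 2, which.max)
  ref <- as.integer(stats::median(peaks))
  shift <- function(x, by) {
    # shift right by `by` samples, padding with edge values
    if (by == 0) return(x)
    n <- length(x)
    if (by > 0) c(rep(x[1], by), x[seq_len(n - by)])
    else c(x[seq(-by + 1, n)], rep(x[n], -by))
  }
  for (j in seq_len(nsw)) {
    by <- ref - peaks[j]
    dV[, j] <- shift(dV[, j], by)
    dI[, j] <- shift(dI[, j], by)
  }
  mdV <- rowMeans(dV); mdI <- rowMeans(dI)
  # onset = last sample before the contiguous suprathreshold run that
  # culminates in the spike's derivative extremum (robust against isolated
  # noise crossings far from the event)
  onsetIdx <- function(d, thr, up) {
    pk <- if (up) which.max(d) else which.min(d)
    if ((up && d[pk] <= thr) || (!up && d[pk] >= thr))
      stop(sprintf(
        "averaged derivative never crosses %g in the averaged signal", thr))
    i <- pk
    while (i > 1 && ((up && d[i - 1] > thr) || (!up && d[i - 1] < thr)))
      i <- i - 1
    i - 1 # last sample before the first suprathreshold sample
  }
  iS <- onsetIdx(mdV, soma_threshold, up = TRUE)
  iB <- onsetIdx(mdI, bleb_threshold, up = FALSE)
  (iB - iS) * dt
}

#' Conduction velocity from a soma-to-bleb latency
#'
#' Converts a measured onset latency into a conduction speed under one of the
#' two spike-initiation conventions: initiation at the middle of the AIS with
#' forward propagation twice as fast as backward (`mid_AIS_2x`), or at the
#' AIS end with a 3x forward/backward ratio (`end_AIS_3x`):
#' `v = (x_bleb - m * x_soma) / T` with `m` = 2 or 3.
#'
#' @param T_ms soma-to-bleb onset delay, ms (> 0)
#' @param x_soma_um distance from the assumed initiation site to the somatic
#'   recording site, um
#' @param x_bleb_um distance from the initiation site to the bleb, um
#' @param assumption `"mid_AIS_2x"` or `"end_AIS_3x"` (no silent default
#'   between the two conventions: choose explicitly)
#' @return object of class `velocity_estimate`: list with `v_m_per_s`, `T_ms`,
#'   `x_soma_um`, `x_bleb_um`, `assumption`, `multiplier`
#' @export
estimateVelocity <- function(T_ms, x_soma_um, x_bleb_um,
                             assumption = c("mid_AIS_2x", "end_AIS_3x")) {
  assumption <- match.arg(assumption)
  if (T_ms <= 0) stop("latency T must be > 0")
  if (x_soma_um < 0 || x_bleb_um < 0) stop("distances must be >= 0")
  m <- if (assumption == "mid_AIS_2x") 2 else 3
  num <- x_bleb_um - m * x_soma_um
  if (num <= 0)
    stop(sprintf(paste0(
      "x_bleb (%g um) must exceed %d * x_soma (%g um) under the %s ",
      "assumption"), x_bleb_um, m, m * x_soma_um, assumption))
  v <- (num / T_ms) / 1000 # um/ms -> m/s
  structure(list(v_m_per_s = v, T_ms = T_ms, x_soma_um = x_soma_um,
                 x_bleb_um = x_bleb_um, assumption = assumption,
                 multiplier = m), class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("Conduction velocity %.3f m/s (%s: v = (x_bleb - %d x_soma)/T;",
              x$v_m_per_s, x$assumption, x$multiplier),
      sprintf("T = %g ms, x_soma = %g um, x_bleb = %g um)\n",
              x$T_ms, x$x_soma_um, x$x_bleb_um))
  invisible(x)
}

#' Full width at half-maximum of a spike waveform
#'
#' Baseline is the pre-spike median (over `pre_frac` of the trace before the
#' peak, or a supplied value); the width is measured at half of the
#' peak-to-baseline amplitude with sub-sample linear interpolation between
#' the crossings flanking the peak. For inward-current spikes use
#' `polarity = "down"`.
#'
#' @param time_ms,x trace (voltage or current)
#' @param polarity "up" (depolarizing peak) or "down" (inward-current peak)
#' @param baseline optional explicit baseline (e.g. the condition's resting
#'   potential); default: median of the pre-peak window
#' @param pre_frac fraction of the samples before the peak used for the
#'   baseline window (default 0.25)
#' @param min_snr minimum (peak - baseline) / baseline-noise-SD to accept a
#'   peak (default 5; skipped when the baseline window is noiseless)
#' @return width, ms
#' @export
spikeWidthFwhm <- function(time_ms, x, polarity = c("up", "down"),
                           baseline = NULL, pre_frac = 0.25, min_snr = 5) {
  polarity <- match.arg(polarity)
  y <- if (polarity == "down") -x else x
  ipk <- which.max(y)
  pre_n <- max(3L, floor(ipk * pre_frac))
  pre <- y[seq_len(min(pre_n, ipk - 1L))]
  b <- if (is.null(baseline)) stats::median(pre) else
    (if (polarity == "down") -baseline else baseline)
  noise <- stats::sd(pre)
  amp <- y[ipk] - b
  if (amp <= 0) stop("no peak above baseline")
  if (is.finite(noise) && noise > 0 && amp < min_snr * noise)
    stop("no peak above ", min_snr, "x the baseline noise")
  half <- b + amp / 2
  # left crossing nearest the peak
  below_l <- which(y[seq_len(ipk)] < half)
  if (!length(below_l)) stop("waveform never below half-maximum before peak")
  iL <- max(below_l)
  tL <- time_ms[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) *
    (time_ms[iL + 1] - time_ms[iL])
  below_r <- which(y < half & seq_along(y) > ipk)
  if (!length(below_r)) stop("waveform never below half-maximum after peak")
  iR <- min(below_r)
  tR <- time_ms[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) *
    (time_ms[iR] - time_ms[iR - 1])
  tR - tL
}
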