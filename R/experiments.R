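#' Spike arrival time at recorded compartments
#'
#' Arrival is the time of maximum dV/dt of the action potential at each
#' compartment (central differences on the recorded trace); alternatively the
#' first upward crossing of a fixed voltage threshold. A compartment whose
#' peak voltage never reaches `min_peak_mV` is treated as not invaded
#' (propagation failure) and reported as NA.
#'
#' @param result a [simulateAxon()] result
#' @param compartments chain indices of the compartments to time (must be
#'   among the recorded ones)
#' @param method "max_dvdt" (default) or "threshold"
#' @param threshold_mV threshold for `method = "threshold"` (default -20)
#' @param min_peak_mV minimum peak voltage to count as a spike (default -20)
#' @return numeric vector of arrival times, ms (NA where no spike)
#' @export
spikeTimes <- function(result, compartments,
                       method = c("max_dvdt", "threshold"),
                       threshold_mV = -20, min_peak_mV = -20) {
  method <- match.arg(method)
  idx <- match(compartments, result$compartments)
  if (anyNA(idx)) stop("requested compartments were not recorded")
  tm <- result$time
  vapply(idx, function(j) {
    v <- result$V[, j]
    if (max(v) < min_peak_mV) return(NA_real_)
    if (method == "max_dvdt") {
      dv <- c(NA, (v[-(1:2)] - v[1:(length(v) - 2)]) /
                (tm[-(1:2)] - tm[1:(length(tm) - 2)]), NA)
      i <- which.max(dv)
      # parabolic vertex through the three samples around the peak gives
      # sub-sample timing (node-to-node intervals are only tens of steps)
      if (i > 2 && i < length(dv) - 1) {
        y1 <- dv[i - 1]; y2 <- dv[i]; y3 <- dv[i + 1]
        den <- y1 - 2 * y2 + y3
        off <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
        tm[i] + off * (tm[i + 1] - tm[i])
      } else tm[i]
    } else {
      k <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV)[1]
      if (is.na(k)) return(NA_real_)
      # linear interpolation between samples
      tm[k] + (threshold_mV - v[k]) / (v[k + 1] - v[k]) * (tm[k + 1] - tm[k])
    }
  }, numeric(1))
}

#' Conduction speed between two compartments
#'
#' Distance along the chain between the two compartment midpoints divided by
#' the spike arrival-time difference.
#'
#' @param model the [axonModel()] that was simulated (for positions)
#' @param result a [simulateAxon()] result recording both compartments
#' @param from,to chain indices of the two compartments
#' @param ... passed to [spikeTimes()]
#' @return speed in m/s (um/ms / 1000)
#' @export
conductionSpeed <- function(model, result, from, to, ...) {
  ts <- spikeTimes(result, c(from, to), ...)
  if (anyNA(ts))
    stop("propagation failure: no spike detected at compartment ",
         paste(c(from, to)[is.na(ts)], collapse = ", "))
  pos <- compartmentPositions(model)
  dist_um <- abs(pos[to] - pos[from])
  dt_ms <- ts[2] - ts[1]
  if (dt_ms <= 0) stop("spike did not travel from 'from' to 'to' (dt <= 0)")
  (dist_um / dt_ms) / 1000
}

setLeak <- function(model, kinds, density, reversal = NULL) {
  model$compartments <- lapply(model$compartments, function(cp) {
    if (cp$kind %in% kinds) {
      cp$leak_density <- density
      if (!is.null(reversal)) cp$leak_reversal <- reversal
    }
    cp
  })
  model
}

#' Calibrate a leak conductance to a target resting potential
#'
#' Bisection on the leak conductance density of the chosen compartment kinds
#' until the steady-state potential of the observed compartment matches the
#' target within `tol_mV`. This mirrors the calibration used to pin the
#' nodal resting potential at -82 mV with the -84 mV K+ leak (recovering a
#' density near 0.113 mS/mm^2) and to set the somatic rest of the truncated
#' model under the nominal -4000 mV leak reversal.
#'
#' @param model an [axonModel()]
#' @param target_Vrest_mV target resting potential, mV
#' @param reversal leak reversal potential, mV, applied to the calibrated
#'   compartments
#' @param kinds compartment kinds whose leak is adjusted (default "node")
#' @param observe chain index of the compartment whose resting potential is
#'   matched (default: a middle compartment of the first calibrated kind)
#' @param lower,upper bracketing densities, mS/mm^2
#' @param tol_mV convergence tolerance, mV
#' @param max_iter bisection iteration cap
#' @param ... passed to [steadyState()]
#' @return list with `density` (mS/mm^2), `achieved_Vrest_mV`, `iterations`,
#'   and `degenerate` (TRUE when the target equals the reversal and any
#'   density satisfies it, in which case the lower bracket is returned)
#' @export
calibrateLeak <- function(model, target_Vrest_mV, reversal,
                          kinds = "node", observe = NULL,
                          lower = 1e-6, upper = 2, tol_mV = 0.05,
                          max_iter = 60L, ...) {
  if (is.null(observe)) {
    cand <- whichCompartments(model, kinds[1])
    if (!length(cand)) stop("model has no compartment of kind ", kinds[1])
    observe <- cand[ceiling(length(cand) / 2)]
  }
  restAt <- function(g) {
    m <- setLeak(model, kinds, g, reversal)
    # a model that fires spontaneously at this density has too little leak:
    # treat it as arbitrarily depolarized for the bracketing logic
    tryCatch(steadyState(m, ...)$V[observe], error = function(e) Inf)
  }
  v_lo <- restAt(lower)
  v_hi <- restAt(upper)
  if (abs(v_lo - v_hi) < tol_mV && abs(v_lo - target_Vrest_mV) < tol_mV) {
    warning("degenerate calibration: the resting potential does not depend ",
            "on the leak density (returning the lower bracket)")
    return(list(density = lower, achieved_Vrest_mV = v_lo, iterations = 0L,
                degenerate = TRUE))
  }
  f_lo <- v_lo - target_Vrest_mV
  f_hi <- v_hi - target_Vrest_mV
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(paste0(
      "target %g mV not bracketable: achievable range is [%.2f, %.2f] mV ",
      "for densities in [%g, %g] mS/mm^2"),
      target_Vrest_mV, min(v_lo, v_hi), max(v_lo, v_hi), lower, upper))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- sqrt(lower * upper) # log-scale bisection: densities span decades
    v_mid <- restAt(mid)
    if (abs(v_mid - target_Vrest_mV) < tol_mV || it >= max_iter) {
      return(list(density = mid, achieved_Vrest_mV = v_mid, iterations = it,
                  degenerate = FALSE))
    }
    if (sign(v_mid - target_Vrest_mV) == sign(f_lo)) {
      lower <- mid; f_lo <- v_mid - target_Vrest_mV
    } else {
      upper <- mid
    }
  }
}

#' Count spikes in a voltage trace
#'
#' Upward crossings of the spike criterion (-50 mV) with a refractory guard
#' against double counting.
#'
#' @param time_ms,V_mV trace
#' @param threshold_mV spike criterion, mV (default -50)
#' @param refractory_ms minimum spacing between counted crossings (default 1)
#' @return integer spike count
#' @export
countSpikes <- function(time_ms, V_mV, threshold_mV = -50,
                        refractory_ms = 1) {
  up <- which(V_mV[-1] >= threshold_mV & V_mV[-length(V_mV)] < threshold_mV)
  if (!length(up)) return(0L)
  t_up <- time_ms[up]
  keep <- c(TRUE, diff(t_up) >= refractory_ms)
  sum(keep)
}

#' Firing rate versus injected current (F-I curve)
#'
#' One 1-s (by default) current step per amplitude is injected at the soma;
#' spikes are upward crossings of -50 mV at the soma with a 1-ms refractory
#' guard; rate is count / duration.
#'
#' @param model an [axonModel()] containing a soma
#' @param amplitudes_nA injected current amplitudes, nA
#' @param duration_s step duration, s (default 1)
#' @param dt time step, ms (default 0.025; firing rates are insensitive to
#'   finer steps)
#' @param threshold_mV spike criterion (default -50)
#' @param init optional [steadyState()] result to reuse across amplitudes
#' @return object of class `fi_curve`: data.frame with `injected_nA` and
#'   `rate_hz`
#' @export
fiCurve <- function(model, amplitudes_nA, duration_s = 1, dt = 0.025,
                    threshold_mV = -50, init = NULL) {
  soma <- whichCompartments(model, "soma")
  if (!length(soma)) stop("model has no soma")
  soma <- soma[1]
  if (is.null(init)) init <- steadyState(model)
  dur_ms <- duration_s * 1000
  rate <- vapply(amplitudes_nA, function(amp) {
    if (amp == 0) {
      # non-spontaneous model at rest: nothing to count
      sim <- simulateAxon(model, stimulusProtocol(soma, 1, dur_ms, 0),
                          dt = dt, t_end_ms = dur_ms + 1,
                          record_stride = 4L, record_compartments = soma,
                          record_peri = FALSE, init = init)
    } else {
      sim <- simulateAxon(model, stimulusProtocol(soma, 1, dur_ms, amp),
                          dt = dt, t_end_ms = dur_ms + 1,
                          record_stride = 4L, record_compartments = soma,
                          record_peri = FALSE, init = init)
    }
    win <- sim$time >= 1 & sim$time <= 1 + dur_ms
    countSpikes(sim$time[win], sim$V[win, 1], threshold_mV) / duration_s
  }, numeric(1))
  structure(data.frame(injected_nA = amplitudes_nA, rate_hz = rate),
            class = c("fi_curve", "data.frame"),
            threshold_mV = threshold_mV, duration_s = duration_s)
}

#' Sweep the adenosine-sensitive Ih density by location
#'
#' Rebuilds the truncated patch-neuron model over a grid of
#' adenosine-sensitive maximal Ih conductance densities placed either in the
#' distal AIS or at the three nodes of Ranvier, and reports for each density
#' the steady-state soma depolarization relative to the zero-density baseline,
#' the mean node resting potential, and (for nodal placement, optionally) the
#' conduction speed between the first and last node under a 1 nA / 100 us
#' soma stimulus.
#'
#' @param location "distal_AIS" or "nodes"
#' @param densities grid of maximal Ih densities, mS/mm^2 (should include 0)
#' @param speed also measure first-to-last-node conduction speed (default
#'   FALSE; only meaningful for `location = "nodes"`)
#' @param builder model-building function taking `gih_distal_ais` and
#'   `gih_nodes` (default [buildPatchNeuron()]); override to sweep variants
#' @param dt_speed time step for the speed runs, ms
#' @param ... passed to the builder
#' @return object of class `gih_sweep`: data.frame with columns
#'   `gih_density`, `location`, `soma_depolarization_mV`, `node_resting_mV`,
#'   `speed_m_per_s` (NA where not measured or propagation failed)
#' @export
sweepGih <- function(location = c("distal_AIS", "nodes"),
                     densities = seq(0, 0.2, by = 0.02),
                     speed = FALSE, builder = buildPatchNeuron,
                     dt_speed = 0.001, ...) {
  location <- match.arg(location)
  if (any(densities < 0)) stop("densities must be >= 0")
  build <- function(g) {
    if (location == "distal_AIS") builder(gih_distal_ais = g, ...)
    else builder(gih_nodes = g, ...)
  }
  base_model <- build(0)
  soma <- whichCompartments(base_model, "soma")[1]
  nodes <- whichCompartments(base_model, "node")
  base_ss <- steadyState(base_model)
  soma0 <- base_ss$V[soma]
  rows <- lapply(densities, function(g) {
    m <- build(g)
    ss <- if (g == 0) base_ss else steadyState(m)
    sp <- NA_real_
    if (speed && length(nodes) >= 2) {
      sp <- tryCatch({
        sim <- simulateAxon(m, stimulusProtocol(soma, 1, 0.1, 1),
                            dt = dt_speed, t_end_ms = 4, init = ss,
                            record_compartments = nodes)
        conductionSpeed(m, sim, nodes[1], nodes[length(nodes)])
      }, error = function(e) NA_real_)
    }
    data.frame(gih_density = g, location = location,
               soma_depolarization_mV = ss$V[soma] - soma0,
               node_resting_mV = if (length(nodes)) mean(ss$V[nodes]) else NA,
               speed_m_per_s = sp)
  })
  structure(do.call(rbind, rows), class = c("gih_sweep", "data.frame"))
}

#' Change in propagating spike width caused by nodal Ih
#'
#' Runs the long-axon model with and without the nodal adenosine-sensitive Ih
#' conductance, extracts the nodal voltage waveform at a mid-axon node, and
#' returns the change in full width at half-maximum (baseline = that
#' condition's resting potential).
#'
#' @param gih_on nodal Ih density in the "on" condition, mS/mm^2
#' @param gih_off nodal Ih density in the "off" condition (default 0)
#' @param builder model-building function taking `nodal_gih` (default
#'   [buildInfiniteAxon()])
#' @param node chain position at which to measure (default: node 25 of the
#'   51-node axon); give a node ordinal, 1-based
#' @param stim_node node ordinal receiving the 1 nA / 100 us stimulus
#' @param dt,t_end_ms integration settings
#' @param ... passed to the builder
#' @return list with `width_on_ms`, `width_off_ms` and `delta_ms`
#'   (on minus off)
#' @export
spikeWidthChange <- function(gih_on, gih_off = 0,
                             builder = buildInfiniteAxon,
                             node = 26L, stim_node = 1L,
                             dt = 0.001, t_end_ms = 6, ...) {
  widthFor <- function(g) {
    m <- builder(nodal_gih = g, ...)
    nodes <- whichCompartments(m, "node")
    sim <- simulateAxon(m, stimulusProtocol(nodes[stim_node], 0.05, 0.1, 1),
                        dt = dt, t_end_ms = t_end_ms,
                        record_compartments = nodes[node],
                        record_peri = FALSE)
    v <- sim$V[, 1]
    if (max(v) < -20) stop("propagation failure: no spike at node ", node)
    spikeWidthFwhm(sim$time, v, polarity = "up", baseline = sim$rest[1])
  }
  w_on <- widthFor(gih_on)
  w_off <- if (identical(gih_on, gih_off)) w_on else widthFor(gih_off)
  list(width_on_ms = w_on, width_off_ms = w_off, delta_ms = w_on - w_off)
}
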