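#' Discretize an axon model into the double-cable state description
#'
#' Splits long myelinated compartments (internodes, paranodes) into
#' sub-segments of at most `max_seg_um`; excitable compartments (soma, AIS,
#' nodes, bleb, micro-links) are kept as single isopotential "nodes", the
#' discretization convention of the double-cable model family this
#' implementation follows. It computes per-segment membrane areas,
#' capacitances and conductances, axial coupling through the axoplasm,
#' periaxonal longitudinal coupling under the myelin, and the transverse
#' axolemma/sheath couplings. Periaxonal state variables exist only for
#' myelinated segments; at a boundary between a myelinated segment and an
#' unmyelinated one the periaxonal space opens to the extracellular bath
#' through the half-segment periaxonal resistance. Chain ends are sealed
#' (no axial current).
#'
#' @param model an [axonModel()]
#' @param max_seg_um maximum sub-segment length, um
#' @return an object of class `cable_system`: a list of per-segment arrays
#'   (areas in cm^2, capacitances in uF, conductances in mS) plus the
#'   segment-to-compartment map and each compartment's midpoint segment
#' @export
assembleSystem <- function(model, max_seg_um = 10) {
  validateAxonModel(model)
  comps <- model$compartments
  ncomp <- length(comps)

  kind <- character(0); comp_of <- integer(0)
  L <- numeric(0); d <- numeric(0); wper <- numeric(0)
  nw <- integer(0); leak_g <- numeric(0); leak_e <- numeric(0)
  dens <- matrix(0, nrow = 0, ncol = 6)
  midpoint_seg <- integer(ncomp)

  for (ci in seq_len(ncomp)) {
    cp <- comps[[ci]]
    nsub <- if (cp$kind %in% kindsMyelinated())
      max(1L, as.integer(ceiling(cp$length_um / max_seg_um))) else 1L
    first <- length(L) + 1L
    L <- c(L, rep(cp$length_um / nsub, nsub))
    d <- c(d, rep(cp$diameter_um, nsub))
    wper <- c(wper, rep(cp$periaxonal_width_nm, nsub))
    nw <- c(nw, rep(cp$n_wraps, nsub))
    leak_g <- c(leak_g, rep(cp$leak_density, nsub))
    leak_e <- c(leak_e, rep(cp$leak_reversal, nsub))
    dens <- rbind(dens, matrix(rep(cp$channel_densities, each = nsub),
                               nrow = nsub))
    kind <- c(kind, rep(cp$kind, nsub))
    comp_of <- c(comp_of, rep(ci, nsub))
    midpoint_seg[ci] <- first + (nsub - 1L) %/% 2L
  }
  colnames(dens) <- names(comps[[1]]$channel_densities)
  nseg <- length(L)
  is_myel <- as.integer(nw > 0)

  # unit conversions: um -> cm, mS/mm^2 -> mS/cm^2 ( *100 )
  A_cm2 <- pi * (d * 1e-4) * (L * 1e-4)
  C_uF <- model$membrane_capacitance * A_cm2
  toG <- function(dens_mSmm2) dens_mSmm2 * 100 * A_cm2 # mS

  # effective myelin sheath: per-membrane values over 2 * n_wraps membranes
  # in series, evaluated at the mid-sheath circumference (the series
  # combination of concentric lamellae is equivalent, to first order, to
  # 2 n membranes at the mean sheath diameter)
  nmem <- pmax(1L, 2L * nw)
  d_my <- d + 2e-3 * wper + 1e-3 * nw * model$myelin_periodicity
  A_my_cm2 <- pi * (d_my * 1e-4) * (L * 1e-4)
  Cmy_uF <- ifelse(is_myel == 1L,
                   model$myelin_capacitance_per_lamella / nmem * A_my_cm2, 0)
  Gmy_mS <- ifelse(is_myel == 1L,
                   model$myelin_conductance_per_lamella * 100 / nmem *
                     A_my_cm2, 0)

  # axial half-resistances through axoplasm (Ohm), conductances in mS
  r_half <- model$axial_resistivity * (L * 1e-4 / 2) /
    (pi * (d * 1e-4 / 2)^2)
  gax_mS <- 1000 / (r_half[-nseg] + r_half[-1])

  # periaxonal longitudinal half-resistances through the annulus pi*d*w
  rp_half <- rep(Inf, nseg)
  myel_idx <- which(is_myel == 1L)
  rp_half[myel_idx] <- model$periaxonal_resistivity *
    (L[myel_idx] * 1e-4 / 2) /
    (pi * (d[myel_idx] * 1e-4) * (wper[myel_idx] * 1e-7))
  gperi_pair_mS <- numeric(nseg - 1L)
  gperi_ground_mS <- numeric(nseg)
  for (i in seq_len(nseg - 1L)) {
    if (is_myel[i] && is_myel[i + 1L]) {
      gperi_pair_mS[i] <- 1000 / (rp_half[i] + rp_half[i + 1L])
    } else if (is_myel[i] && !is_myel[i + 1L]) {
      gperi_ground_mS[i] <- gperi_ground_mS[i] + 1000 / rp_half[i]
    } else if (!is_myel[i] && is_myel[i + 1L]) {
      gperi_ground_mS[i + 1L] <- gperi_ground_mS[i + 1L] + 1000 / rp_half[i + 1L]
    }
  }

  excitable <- as.integer(rowSums(dens) > 0)

  structure(list(
    nseg = nseg, kind = kind, comp_of = comp_of,
    midpoint_seg = midpoint_seg,
    length_um = L, diameter_um = d,
    is_myel = is_myel, excitable = excitable,
    A_cm2 = A_cm2, C_uF = C_uF,
    gL_mS = toG(leak_g), eL_mV = leak_e,
    Gnaf_mS = toG(dens[, "naf"]), Gnap_mS = toG(dens[, "nap"]),
    Gks_mS = toG(dens[, "ks"]), Gklt_mS = toG(dens[, "klt"]),
    Gihs_mS = toG(dens[, "ih_sensitive"]),
    Gihi_mS = toG(dens[, "ih_insensitive"]),
    Cmy_uF = Cmy_uF, Gmy_mS = Gmy_mS,
    gax_mS = gax_mS, gperi_pair_mS = gperi_pair_mS,
    gperi_ground_mS = gperi_ground_mS,
    kinetics = model$kinetics,
    max_seg_um = max_seg_um
  ), class = "cable_system")
}

kineticsVector <- function(kin) {
  nm <- c("m_a_A", "m_a_V", "m_a_k", "m_b_A", "m_b_V", "m_b_k",
          "h_a_A", "h_a_V", "h_a_k", "h_b_A", "h_b_V", "h_b_k",
          "p_a_A", "p_a_V", "p_a_k", "p_b_A", "p_b_V", "p_b_k",
          "s_a_A", "s_a_V", "s_a_k", "s_b_A", "s_b_V", "s_b_k",
          "w_a_A", "w_a_V", "w_a_k", "w_b_A", "w_b_V", "w_b_k",
          "e_na", "e_k", "e_h",
          "ih_vhalf_sensitive", "ih_vhalf_insensitive",
          "ih_slope", "ih_tau")
  miss <- setdiff(nm, names(kin))
  if (length(miss)) stop("kinetics list missing: ", paste(miss, collapse = ", "))
  as.numeric(unlist(kin[nm]))
}

# initial state: V at per-segment leak reversal (clamped to a physiological
# floor for the -4000 mV nominal-reversal device), U = 0, gates at their
# steady state for V
initialState <- function(sys, V0 = NULL) {
  n <- sys$nseg
  V <- if (is.null(V0)) pmax(sys$eL_mV, -90) else rep(V0, n)
  kin <- sys$kinetics
  g <- gateSteadyStates(V, kin)
  qs <- ihSteadyState(V, kin$ih_vhalf_sensitive, kin$ih_slope)
  qi <- ihSteadyState(V, kin$ih_vhalf_insensitive, kin$ih_slope)
  c(V, rep(0, n), g$m, g$h, g$p, g$s, g$w, qs, qi)
}

#' Define a current-clamp stimulus protocol
#'
#' @param target compartment index in the chain (see [whichCompartments()])
#' @param onset_ms,duration_ms step timing, ms
#' @param amplitude_nA step amplitude, nA
#' @return object of class `stimulus_protocol`; multiple steps can be given
#'   as vectors
#' @export
stimulusProtocol <- function(target, onset_ms, duration_ms, amplitude_nA) {
  stopifnot(length(onset_ms) == length(duration_ms),
            length(onset_ms) == length(amplitude_nA),
            length(target) %in% c(1L, length(onset_ms)))
  if (any(duration_ms <= 0)) stop("stimulus durations must be > 0")
  if (any(!is.finite(amplitude_nA))) stop("stimulus amplitudes must be finite")
  structure(list(target = as.integer(target), onset_ms = onset_ms,
                 duration_ms = duration_ms, amplitude_nA = amplitude_nA,
                 mode = "current_clamp"), class = "stimulus_protocol")
}

runIntegrator <- function(sys, state, dt, nsteps, t0 = 0,
                          stim = NULL, record_stride = 0L,
                          record_segs = integer(0), record_peri = FALSE) {
  if (is.null(stim)) {
    seg <- integer(0); on <- numeric(0); off <- numeric(0); amp <- numeric(0)
  } else {
    tgt <- rep(stim$target, length.out = length(stim$onset_ms))
    seg <- sys$midpoint_seg[tgt] - 1L # 0-based
    on <- stim$onset_ms
    off <- stim$onset_ms + stim$duration_ms
    amp <- stim$amplitude_nA * 1e-3 # nA -> uA
  }
  .cable_integrate(sys, state, kineticsVector(sys$kinetics),
                   dt, as.integer(nsteps), t0,
                   as.integer(seg), on, off, amp,
                   as.integer(record_stride), as.integer(record_segs - 1L),
                   record_peri)
}

#' Resting steady state of a model
#'
#' Finds the stimulus-free fixed point by implicit relaxation: the system is
#' integrated without stimulus using a long time step until the maximum
#' |dV/dt| over all axonal and periaxonal states falls below `tol`. At least
#' `min_time_ms` of simulated time is always run (the slow Ih gate needs
#' seconds to settle); relaxation is deterministic and seed-free. If the
#' voltage keeps changing after `max_time_ms` the model is likely firing
#' spontaneously and an error is raised rather than averaging over the
#' oscillation.
#'
#' @param model an [axonModel()] or a pre-assembled `cable_system`
#' @param tol convergence tolerance on max |dV/dt|, mV/ms
#' @param dt_relax relaxation time step, ms
#' @param min_time_ms,max_time_ms relaxation time bounds, ms
#' @param max_seg_um discretization passed to [assembleSystem()]
#' @return list with `V` (per-compartment resting potential, mV, at the
#'   compartment midpoint), `V_seg` (per segment), `state` (full solver
#'   state), `system`, and `max_dvdt`
#' @export
steadyState <- function(model, tol = 1e-6, dt_relax = 0.5,
                        min_time_ms = 2000, max_time_ms = 10000,
                        max_seg_um = 10) {
  sys <- if (inherits(model, "cable_system")) model else
    assembleSystem(model, max_seg_um)
  state <- initialState(sys)
  t <- 0
  chunk_ms <- 500
  nst <- as.integer(round(chunk_ms / dt_relax))
  repeat {
    out <- runIntegrator(sys, state, dt_relax, nst, t0 = t)
    state <- out$state
    t <- t + chunk_ms
    if (t >= min_time_ms && out$max_dvdt < tol) break
    if (t >= max_time_ms) {
      stop(sprintf(paste0(
        "steady state did not converge after %g ms (max |dV/dt| = %.3g ",
        "mV/ms): the model may be firing spontaneously"), t, out$max_dvdt))
    }
  }
  n <- sys$nseg
  V_seg <- state[seq_len(n)]
  list(V = V_seg[sys$midpoint_seg], V_seg = V_seg, state = state,
       system = sys, max_dvdt = out$max_dvdt)
}

#' Simulate an axon model under a stimulus protocol
#'
#' Integrates the double-cable system from its resting steady state (found by
#' relaxation before t = 0 unless an explicit starting state is supplied).
#' Voltages are recorded at every compartment midpoint (or a chosen subset)
#' every `record_stride` steps.
#'
#' @param model an [axonModel()]
#' @param stimulus a [stimulusProtocol()] or NULL
#' @param dt time step, ms (default 0.001 = 1 us, appropriate for speed
#'   measurements; 0.025 ms suits 1-s firing-rate runs)
#' @param t_end_ms end time, ms
#' @param record_stride record every this many steps (default 1)
#' @param record_compartments compartment indices to record (default: all)
#' @param record_peri also record periaxonal potentials (default TRUE)
#' @param init optional starting state: result of [steadyState()] (its
#'   `state`/`system`) to skip the settling run
#' @param max_seg_um discretization limit, um
#' @return object of class `simulation_result` with fields `time` (ms),
#'   `V` (mV, time x compartment), `V_peri` (mV, myelinated compartments,
#'   NA elsewhere), `injected_nA`, `compartments`, `position_um`, `rest`
#'   (pre-stimulus resting potentials), and solver metadata
#' @export
simulateAxon <- function(model, stimulus = NULL, dt = 0.001, t_end_ms = 10,
                         record_stride = 1L, record_compartments = NULL,
                         record_peri = TRUE, init = NULL, max_seg_um = 10) {
  if (dt <= 0) stop("dt must be > 0")
  if (!is.null(stimulus) &&
      t_end_ms < max(stimulus$onset_ms + stimulus$duration_ms))
    stop("t_end_ms must extend beyond the stimulus")
  if (is.null(init)) {
    ss <- steadyState(model, max_seg_um = max_seg_um)
    sys <- ss$system
    state <- ss$state
  } else {
    sys <- init$system
    state <- init$state
  }
  ncomp <- length(sys$midpoint_seg)
  rec_comp <- if (is.null(record_compartments)) seq_len(ncomp) else
    as.integer(record_compartments)
  rec_segs <- sys$midpoint_seg[rec_comp]
  nsteps <- as.integer(ceiling(t_end_ms / dt))
  out <- runIntegrator(sys, state, dt, nsteps, t0 = 0, stim = stimulus,
                       record_stride = record_stride,
                       record_segs = rec_segs, record_peri = record_peri)
  tm <- out$time
  inj <- numeric(length(tm))
  if (!is.null(stimulus)) {
    for (k in seq_along(stimulus$onset_ms)) {
      onk <- stimulus$onset_ms[k]
      inj[tm >= onk & tm < onk + stimulus$duration_ms[k]] <-
        inj[tm >= onk & tm < onk + stimulus$duration_ms[k]] +
        stimulus$amplitude_nA[k]
    }
  }
  Vp <- if (record_peri) {
    vp <- out$U
    vp[, sys$is_myel[rec_segs] == 0L] <- NA_real_
    vp
  } else NULL
  pos <- cumsum(vapply(seq_len(ncomp), function(ci) {
    segs <- which(sys$comp_of == ci)
    sum(sys$length_um[segs])
  }, numeric(1)))
  lens <- diff(c(0, pos))
  structure(list(
    time = tm, V = out$V, V_peri = Vp, injected_nA = inj,
    compartments = rec_comp,
    kind = sys$kind[rec_segs],
    position_um = (pos - lens / 2)[rec_comp],
    rest = state[seq_len(sys$nseg)][rec_segs],
    dt = dt, record_stride = record_stride,
    max_seg_um = sys$max_seg_um,
    stimulus = stimulus
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation: %d compartments recorded, t = %g..%g ms (dt = %g ms)\n",
              ncol(x$V), min(x$time), max(x$time), x$dt))
  cat(sprintf("Voltage range %.1f .. %.1f mV\n", min(x$V), max(x$V)))
  invisible(x)
}

#' Tidy long-format export of a simulation result
#'
#' @param x a `simulation_result`
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused)
#' @return data.frame with columns compartment, kind, position_um, time_ms,
#'   V_mV, V_peri_mV
#' @export
as.data.frame.simulation_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  nt <- length(x$time); nc <- ncol(x$V)
  data.frame(
    compartment = rep(x$compartments, each = nt),
    kind = rep(x$kind, each = nt),
    position_um = rep(x$position_um, each = nt),
    time_ms = rep(x$time, nc),
    V_mV = as.vector(x$V),
    V_peri_mV = if (is.null(x$V_peri)) NA_real_ else as.vector(x$V_peri)
  )
}

#' Save / load a simulation result container
#'
#' The result is stored as an RDS container holding the named arrays (time,
#' V_axon, V_periaxonal, injected current and metadata); a tidy CSV of the
#' long-format table can be written alongside for plotting.
#'
#' @param result a `simulation_result`
#' @param path output path (`.rds`)
#' @param csv optional path for the tidy long-format CSV export
#' @return `path`, invisibly
#' @export
saveSimulationResult <- function(result, path, csv = NULL) {
  saveRDS(result, path)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(result), csv, row.names = FALSE)
  invisible(path)
}

#' @rdname saveSimulationResult
#' @export
readSimulationResult <- function(path) readRDS(path)
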