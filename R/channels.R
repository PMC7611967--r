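#' Gating-rate and channel-parameter defaults
#'
#' The nodal action-potential machinery follows the double-cable lineage of
#' myelinated-axon models: a fast Nav (m^3 h), a persistent Nav (p^3) and a
#' slow Kv (s) at the node, plus a low-threshold Kv (w) restricted to the
#' axon initial segment. Rate constants are expressed in ms^-1 at body
#' temperature and every one of them can be overridden, so alternative
#' kinetics from the same model family can be dropped in without touching
#' the solver.
#'
#' Rates use two functional forms. Linoid rates are
#' \code{A (V - V0) / (1 - exp(-(V - V0)/k))} (or the mirrored version for
#' closing rates); sigmoid rates are \code{A / (1 + exp((V - V0)/k))} with the
#' sign of \code{k} carried in the constant.
#'
#' Ih is a single-gate conductance with Boltzmann steady state
#' \code{1/(1 + exp((V - v_half)/slope))} (activated by hyperpolarization,
#' \code{slope > 0}) and a voltage-independent time constant. Two variants are
#' shipped: the cAMP/adenosine-insensitive somatic form with midpoint
#' -103.5 mV and the adenosine-sensitive form whose midpoint sits at -80 mV,
#' i.e. substantially activated at rest. Both reverse at -23 mV.
#'
#' @return Named list of rate constants, reversal potentials and Ih
#'   parameters (mV, ms, ms^-1).
#' @export
defaultKinetics <- function() {
  list(
    # fast Nav activation m (linoid open / mirrored linoid close)
    m_a_A = 6.57,     m_a_V = -20.4,  m_a_k = 10.3,
    m_b_A = 0.304,    m_b_V = -25.7,  m_b_k = 9.16,
    # fast Nav inactivation h (mirrored linoid open / sigmoid close)
    h_a_A = 0.34,     h_a_V = -114,   h_a_k = 11,
    h_b_A = 12.6,     h_b_V = -31.8,  h_b_k = -13.4,
    # persistent Nav p
    p_a_A = 0.0353,   p_a_V = -27,    p_a_k = 10.2,
    p_b_A = 0.000883, p_b_V = -34,    p_b_k = 10,
    # slow Kv s (both rates sigmoid)
    s_a_A = 0.3,      s_a_V = -53,    s_a_k = -5,
    s_b_A = 0.03,     s_b_V = -90,    s_b_k = -1,
    # low-threshold Kv w (AIS only): Kv1-like single gate. With these
    # mirrored sigmoid rates the steady state is a Boltzmann with midpoint
    # -60 mV and slope 10 mV and the time constant is ~1.7 ms: slightly open
    # at rest and activating well below the spike threshold -- the properties
    # that keep the AIS resting potential stable and allow repetitive
    # action-potential trains under sustained somatic current injection
    w_a_A = 0.6,      w_a_V = -60,    w_a_k = -10,
    w_b_A = 0.6,      w_b_V = -60,    w_b_k = 10,
    e_na = 50, e_k = -84, e_h = -23,
    ih_vhalf_sensitive = -80, ih_vhalf_insensitive = -103.5,
    ih_slope = 9, ih_tau = 50
  )
}

#' Steady-state activation of the hyperpolarization-activated current Ih
#'
#' Boltzmann curve oriented so that activation approaches 1 with
#' hyperpolarization and 0 with depolarization; \code{slope > 0}.
#' A depolarizing shift of \code{v_half} (e.g. -103.5 to -80 mV under
#' cAMP/adenosine) increases activation at every voltage.
#'
#' @param V membrane potential, mV (vectorised)
#' @param v_half activation midpoint, mV
#' @param slope Boltzmann slope factor, mV (> 0)
#' @return activation fraction in \[0, 1\]
#' @export
ihSteadyState <- function(V, v_half, slope = 9) {
  if (!is.numeric(slope) || slope == 0) stop("'slope' must be non-zero")
  1 / (1 + exp((V - v_half) / slope))
}

#' Channel constructors
#'
#' Lightweight descriptions of a gated conductance, an Ih variant and an
#' ohmic leak, used by [channelCurrent()] and carried in compartment
#' channel-density maps. Densities are in mS/mm^2, potentials in mV.
#'
#' @param name channel name
#' @param gbar fully-activated conductance density, mS/mm^2
#' @param reversal reversal potential, mV
#' @param gates list of gates, each `list(exponent =, inf = function(V),
#'   tau = function(V))`
#' @return an object of class `gated_channel`, `ih_channel` or `leak_current`
#' @export
gatedChannel <- function(name, gbar, reversal, gates) {
  stopifnot(is.character(name), gbar >= 0, is.list(gates))
  structure(list(name = name, gbar = gbar, reversal = reversal,
                 gates = gates), class = "gated_channel")
}

#' @rdname gatedChannel
#' @param v_half Ih activation midpoint, mV
#' @param slope Ih Boltzmann slope, mV
#' @param tau Ih activation time constant, ms (voltage-independent)
#' @param cAMP_sensitive logical; TRUE for the adenosine/cAMP-shifted variant
#' @export
ihChannel <- function(gbar, v_half = -103.5, slope = 9, reversal = -23,
                      tau = 50, cAMP_sensitive = FALSE) {
  stopifnot(gbar >= 0, slope > 0, tau > 0)
  structure(list(name = if (cAMP_sensitive) "ih_sensitive" else "ih_insensitive",
                 gbar = gbar, v_half = v_half, slope = slope,
                 reversal = reversal, tau = tau,
                 cAMP_sensitive = cAMP_sensitive), class = "ih_channel")
}

#' @rdname gatedChannel
#' @param density leak conductance density, mS/mm^2
#' @export
leakCurrent <- function(density, reversal = -84) {
  stopifnot(density >= 0)
  structure(list(name = "leak", gbar = density, reversal = reversal),
            class = "leak_current")
}

#' Membrane current density of a channel at a given voltage
#'
#' Ohmic conductance-based current, outward positive:
#' \code{gbar * prod(gate^exponent) * (V - reversal)}. The leak ignores gate
#' state. Ih takes a single gate fraction (its activation variable).
#'
#' @param channel a [gatedChannel()], [ihChannel()] or [leakCurrent()]
#' @param V membrane potential, mV
#' @param gate_states numeric vector of per-gate open fractions in \[0, 1\]
#'   (ignored for leak)
#' @return current density, uA/mm^2, outward positive
#' @export
channelCurrent <- function(channel, V, gate_states = numeric()) {
  if (length(gate_states) &&
      (any(gate_states < 0) || any(gate_states > 1))) {
    stop("gate_states must lie in [0, 1]")
  }
  open <- if (inherits(channel, "leak_current")) {
    1
  } else if (inherits(channel, "ih_channel")) {
    if (length(gate_states) != 1) stop("Ih takes exactly one gate state")
    gate_states[[1]]
  } else {
    exps <- vapply(channel$gates, function(g) g$exponent, numeric(1))
    prod(gate_states ^ exps)
  }
  channel$gbar * open * (V - channel$reversal)
}

# rate helpers shared with tests (mirror the compiled kernels)
rateLinoid <- function(A, V0, k, v) {
  x <- (v - V0) / k
  ifelse(abs(x) < 1e-7, A * k, A * (v - V0) / (1 - exp(-x)))
}
rateLinoidNeg <- function(A, V0, k, v) {
  x <- (v - V0) / k
  ifelse(abs(x) < 1e-7, A * k, A * (V0 - v) / (1 - exp(x)))
}
rateSigmoid <- function(A, V0, k, v) A / (1 + exp((v - V0) / k))

#' Steady-state gate values for the voltage-gated channel set
#'
#' @param V membrane potential, mV
#' @param kin kinetics list from [defaultKinetics()]
#' @return named list of steady-state fractions (m, h, p, s, w)
#' @keywords internal
gateSteadyStates <- function(V, kin = defaultKinetics()) {
  ss <- function(a, b) a / (a + b)
  list(
    m = ss(rateLinoid(kin$m_a_A, kin$m_a_V, kin$m_a_k, V),
           rateLinoidNeg(kin$m_b_A, kin$m_b_V, kin$m_b_k, V)),
    h = ss(rateLinoidNeg(kin$h_a_A, kin$h_a_V, kin$h_a_k, V),
           rateSigmoid(kin$h_b_A, kin$h_b_V, kin$h_b_k, V)),
    p = ss(rateLinoid(kin$p_a_A, kin$p_a_V, kin$p_a_k, V),
           rateLinoidNeg(kin$p_b_A, kin$p_b_V, kin$p_b_k, V)),
    s = ss(rateSigmoid(kin$s_a_A, kin$s_a_V, kin$s_a_k, V),
           rateSigmoid(kin$s_b_A, kin$s_b_V, kin$s_b_k, V)),
    w = ss(rateSigmoid(kin$w_a_A, kin$w_a_V, kin$w_a_k, V),
           rateSigmoid(kin$w_b_A, kin$w_b_V, kin$w_b_k, V))
  )
}

#' Default channel-density map per compartment kind
#'
#' Nodes of Ranvier carry fast Nav 10, persistent Nav 0.01 and slow Kv
#' 0.4 mS/mm^2, a K+ leak of 0.113 mS/mm^2 reversing at -84 mV, and the
#' adenosine-gated Ih at 0 (no receptor activation) or 0.1565 mS/mm^2
#' (1.41 x the distal-AIS density of 0.111, the immunohistochemical nodal
#' enrichment). AIS compartments add a low-threshold Kv at 0.4 mS/mm^2;
#' soma and proximal AIS carry the cAMP-insensitive Ih at 0.0033 mS/mm^2;
#' the distal AIS carries the adenosine-sensitive Ih at 0.111 mS/mm^2 when
#' the adenosine flag is set. Internodes, paranodes, micro-links and the
#' terminal bleb carry no voltage-gated conductances (leak only).
#'
#' @param location compartment kind, one of [compartmentKinds()]
#' @param adenosine logical: are A2a receptors activated (adds the
#'   cAMP-shifted Ih to node / distal AIS)?
#' @return named numeric vector of densities, mS/mm^2, over the channel
#'   names `naf`, `nap`, `ks`, `klt`, `ih_sensitive`, `ih_insensitive`
#' @export
defaultChannelSet <- function(location, adenosine = FALSE) {
  location <- match.arg(location, compartmentKinds())
  z <- c(naf = 0, nap = 0, ks = 0, klt = 0,
         ih_sensitive = 0, ih_insensitive = 0)
  nav_kv <- c(naf = 10, nap = 0.01, ks = 0.4)
  switch(location,
    node = {
      z[names(nav_kv)] <- nav_kv
      z["ih_sensitive"] <- if (adenosine) 0.1565 else 0
    },
    proximal_AIS = {
      z[names(nav_kv)] <- nav_kv
      z["klt"] <- 0.4
      z["ih_insensitive"] <- 0.0033
    },
    distal_AIS = {
      z[names(nav_kv)] <- nav_kv
      z["klt"] <- 0.4
      z["ih_sensitive"] <- if (adenosine) 0.111 else 0
    },
    soma = {
      z["ih_insensitive"] <- 0.0033
    },
    # internode, paranode, micro_link, bleb: passive
    z
  )
  z
}
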