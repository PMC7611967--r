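#' Compartment kinds recognised by the model
#'
#' @return character vector of valid compartment kinds
#' @export
compartmentKinds <- function() {
  c("soma", "proximal_AIS", "distal_AIS", "node", "paranode",
    "internode", "micro_link", "bleb")
}

kindsMyelinated <- function() c("paranode", "internode")

#' Create a single compartment specification
#'
#' A compartment is one cylindrical piece of the axon chain: an excitable,
#' unmyelinated piece (soma, AIS, node of Ranvier, terminal bleb, micro-link)
#' or a myelin-wrapped piece (internode body or its paranodal end zones).
#' Myelinated compartments carry a periaxonal space -- the thin conducting
#' layer between axolemma and innermost myelin membrane that forms the second
#' cable of the double-cable model.
#'
#' @param kind one of [compartmentKinds()]
#' @param length_um,diameter_um cylinder dimensions, micrometres (> 0;
#'   micro-links use the nominal 1e-7 um)
#' @param n_wraps integer number of myelin wraps (0 for unmyelinated kinds,
#'   > 0 for internode/paranode)
#' @param periaxonal_width_nm width of the submyelin (periaxonal) space in
#'   nanometres; only meaningful when `n_wraps > 0`
#' @param channel_densities named numeric vector of voltage-gated channel
#'   densities in mS/mm^2 (names as in [defaultChannelSet()]); defaults to the
#'   kind's default set
#' @param leak_density leak conductance density, mS/mm^2
#' @param leak_reversal leak reversal potential, mV
#' @return an object of class `compartment_spec`
#' @export
compartmentSpec <- function(kind, length_um, diameter_um,
                            n_wraps = 0L, periaxonal_width_nm = 0,
                            channel_densities = defaultChannelSet(kind),
                            leak_density = 0, leak_reversal = -84) {
  kind <- match.arg(kind, compartmentKinds())
  if (!is.numeric(length_um) || length_um <= 0)
    stop("compartment length must be > 0 (got ", length_um, ")")
  if (!is.numeric(diameter_um) || diameter_um <= 0)
    stop("compartment diameter must be > 0 (got ", diameter_um, ")")
  if (n_wraps < 0) stop("n_wraps must be >= 0")
  myel <- kind %in% kindsMyelinated()
  if (myel && n_wraps == 0)
    stop(kind, " compartments must have n_wraps > 0")
  if (!myel && n_wraps > 0)
    stop(kind, " compartments must be unmyelinated (n_wraps = 0)")
  if (myel && periaxonal_width_nm <= 0)
    stop("myelinated compartments need periaxonal_width_nm > 0")
  cd <- c(naf = 0, nap = 0, ks = 0, klt = 0,
          ih_sensitive = 0, ih_insensitive = 0)
  if (length(channel_densities)) {
    unknown <- setdiff(names(channel_densities), names(cd))
    if (length(unknown))
      stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
    if (any(channel_densities < 0)) stop("channel densities must be >= 0")
    cd[names(channel_densities)] <- channel_densities
  }
  if (myel && any(cd > 0))
    stop("myelinated compartments carry no voltage-gated channels")
  if (leak_density < 0) stop("leak_density must be >= 0")
  structure(list(kind = kind,
                 length_um = as.numeric(length_um),
                 diameter_um = as.numeric(diameter_um),
                 n_wraps = as.integer(n_wraps),
                 periaxonal_width_nm = as.numeric(periaxonal_width_nm),
                 channel_densities = cd,
                 leak_density = as.numeric(leak_density),
                 leak_reversal = as.numeric(leak_reversal)),
            class = "compartment_spec")
}

#' Lateral membrane area of a compartment, um^2
#' @param comp a [compartmentSpec()]
#' @return area in um^2 (pi * diameter * length)
#' @export
compartmentArea <- function(comp) {
  pi * comp$diameter_um * comp$length_um
}

#' Assemble an axon model from an ordered compartment chain
#'
#' Bundles the compartment chain with the global electrical constants of the
#' double-cable model. Per-lamella myelin electrical properties follow the
#' series-membrane convention: each wrap contributes two membranes in series,
#' so the effective sheath capacitance (conductance) per unit axolemma area is
#' the per-membrane value divided by `2 * n_wraps`.
#'
#' @param compartments list of [compartmentSpec()] objects, in chain order
#' @param membrane_capacitance specific membrane capacitance, uF/cm^2
#' @param myelin_periodicity radial spacing of myelin wraps, nm
#' @param axial_resistivity axoplasmic resistivity, Ohm cm
#' @param periaxonal_resistivity resistivity of the periaxonal space, Ohm cm
#' @param myelin_capacitance_per_lamella capacitance of one myelin membrane,
#'   uF/cm^2
#' @param myelin_conductance_per_lamella conductance of one myelin membrane,
#'   mS/mm^2
#' @param kinetics gating-rate constants, see [defaultKinetics()]
#' @return an object of class `axon_model`
#' @export
axonModel <- function(compartments,
                      membrane_capacitance = 0.9,
                      myelin_periodicity = 15.6,
                      axial_resistivity = 70,
                      periaxonal_resistivity = 70,
                      myelin_capacitance_per_lamella = 0.9,
                      myelin_conductance_per_lamella = 0.01,
                      kinetics = defaultKinetics()) {
  if (!length(compartments)) stop("empty compartment chain")
  ok <- vapply(compartments, inherits, logical(1), "compartment_spec")
  if (!all(ok)) stop("all compartments must be compartment_spec objects")
  if (membrane_capacitance <= 0) stop("membrane_capacitance must be > 0")
  if (axial_resistivity <= 0 || periaxonal_resistivity <= 0)
    stop("resistivities must be > 0")
  model <- structure(list(
    compartments = compartments,
    membrane_capacitance = membrane_capacitance,
    myelin_periodicity = myelin_periodicity,
    axial_resistivity = axial_resistivity,
    periaxonal_resistivity = periaxonal_resistivity,
    myelin_capacitance_per_lamella = myelin_capacitance_per_lamella,
    myelin_conductance_per_lamella = myelin_conductance_per_lamella,
    kinetics = kinetics
  ), class = "axon_model")
  validateAxonModel(model)
  model
}

#' Validate an axon model's chain
#'
#' Checks the physical validity of the compartment chain: positive
#' dimensions, wrap counts consistent with kind, no two distinct myelinated
#' internode bodies directly adjacent (paranode-internode contact within one
#' sheath is allowed), and paranodal periaxonal width not exceeding that of
#' the adjacent internode.
#'
#' @param model an [axonModel()]
#' @return invisibly TRUE; stops with a message on violation
#' @export
validateAxonModel <- function(model) {
  comps <- model$compartments
  kinds <- vapply(comps, function(x) x$kind, character(1))
  if (length(comps) > 1) {
    for (i in seq_len(length(comps) - 1L)) {
      if (kinds[i] == "internode" && kinds[i + 1L] == "internode")
        stop("two internode bodies adjacent at positions ", i, "/", i + 1,
             ": separate them with a node, paranode or micro_link")
    }
    for (i in seq_along(comps)) {
      if (kinds[i] != "paranode") next
      nb <- c(if (i > 1) i - 1L, if (i < length(comps)) i + 1L)
      adj_in <- nb[kinds[nb] == "internode"]
      for (j in adj_in) {
        if (comps[[i]]$periaxonal_width_nm >
            comps[[j]]$periaxonal_width_nm + 1e-12)
          stop("paranode periaxonal width exceeds adjacent internode width ",
               "at position ", i)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.axon_model <- function(x, ...) {
  kinds <- vapply(x$compartments, function(c) c$kind, character(1))
  tab <- table(factor(kinds, levels = compartmentKinds()))
  tot <- sum(vapply(x$compartments, function(c) c$length_um, numeric(1)))
  cat("Double-cable axon model:", length(kinds), "compartments,",
      sprintf("%.1f um total length\n", tot))
  print(tab[tab > 0])
  cat(sprintf("Cm = %.2f uF/cm^2, rho_axial = %g Ohm cm, rho_periaxonal = %g Ohm cm\n",
              x$membrane_capacitance, x$axial_resistivity,
              x$periaxonal_resistivity))
  invisible(x)
}

#' @export
print.compartment_spec <- function(x, ...) {
  cat(sprintf("%s: %g um x %g um", x$kind, x$length_um, x$diameter_um))
  if (x$n_wraps > 0)
    cat(sprintf(", %d wraps, periaxonal %g nm", x$n_wraps,
                x$periaxonal_width_nm))
  on <- x$channel_densities[x$channel_densities > 0]
  if (length(on))
    cat("; channels:", paste(names(on), on, sep = "=", collapse = " "))
  cat(sprintf("; leak %g mS/mm^2 @ %g mV\n", x$leak_density, x$leak_reversal))
  invisible(x)
}

#' g-ratio of a myelinated fiber
#'
#' Ratio of axon diameter to outer fiber diameter, counting the periaxonal
#' space and `n_wraps` myelin wraps of the given radial periodicity in the
#' sheath:
#' `d / (d + 2 (periaxonal_width + n_wraps * periodicity))`.
#' Equals 1 with no sheath and decreases strictly with wrap count and
#' periaxonal width.
#'
#' @param axon_diameter_um axon diameter, um
#' @param n_wraps number of myelin wraps (>= 0)
#' @param periodicity_nm myelin wrap periodicity, nm (default 15.6)
#' @param periaxonal_width_nm periaxonal space width, nm (default 15)
#' @return dimensionless g-ratio in (0, 1]
#' @export
computeGRatio <- function(axon_diameter_um, n_wraps,
                          periodicity_nm = 15.6, periaxonal_width_nm = 15) {
  if (any(axon_diameter_um <= 0)) stop("axon diameter must be > 0")
  if (any(n_wraps < 0) || any(periodicity_nm < 0) ||
      any(periaxonal_width_nm < 0)) stop("negative inputs not allowed")
  sheath_um <- (periaxonal_width_nm + n_wraps * periodicity_nm) * 1e-3
  axon_diameter_um / (axon_diameter_um + 2 * sheath_um)
}

#' Smallest wrap count reaching a target g-ratio
#'
#' @inheritParams computeGRatio
#' @param target target g-ratio (default 0.8); returns the smallest integer
#'   wrap count whose g-ratio is <= target
#' @return integer wrap count
#' @export
wrapsForGRatio <- function(axon_diameter_um, target = 0.8,
                           periodicity_nm = 15.6, periaxonal_width_nm = 15) {
  n <- 0L
  while (computeGRatio(axon_diameter_um, n, periodicity_nm,
                       periaxonal_width_nm) > target) {
    n <- n + 1L
    if (n > 10000L) stop("target g-ratio not reachable")
  }
  n
}

#' Build the uniform long ("infinite") callosal axon model
#'
#' A uniform myelinated axon of `n_nodes` nodes of Ranvier alternating with
#' `n_nodes - 1` internodes. Each internode's terminal 1.9 um at both ends is
#' represented as a paranode compartment whose periaxonal space is nearly
#' sealed (0.0123 nm); the internode body keeps the 15 nm periaxonal width.
#' Nodes carry the full excitable channel set (see [defaultChannelSet()]) and
#' optionally an adenosine-gated Ih.
#'
#' @param n_nodes number of nodes (default 51; 1 gives a single space-clamped
#'   node)
#' @param node_length_um,node_diameter_um node dimensions (1.5 x 0.64 um)
#' @param internode_length_um,internode_diameter_um internode dimensions
#'   (81.7 x 0.73 um, paranodes included in the length)
#' @param paranode_length_um paranodal end-zone length (1.9 um)
#' @param n_wraps myelin wraps (5, giving g-ratio close to 0.8)
#' @param periaxonal_width_nm internodal periaxonal width, nm (15)
#' @param paranode_periaxonal_width_nm paranodal periaxonal width, nm (0.0123)
#' @param nodal_gih adenosine-sensitive Ih density at each node, mS/mm^2
#'   (0 = no receptor activation; 0.1565 mimics A2a activation)
#' @param node_leak_density nodal K+ leak density, mS/mm^2 (0.113)
#' @param leak_reversal nodal/internodal leak reversal, mV (-84)
#' @param internode_leak_density passive internodal axolemma leak, mS/mm^2
#' @param ... further arguments passed to [axonModel()] (resistivities,
#'   myelin constants, kinetics)
#' @return an [axonModel()]
#' @export
buildInfiniteAxon <- function(n_nodes = 51L,
                              node_length_um = 1.5,
                              node_diameter_um = 0.64,
                              internode_length_um = 81.7,
                              internode_diameter_um = 0.73,
                              paranode_length_um = 1.9,
                              n_wraps = 5L,
                              periaxonal_width_nm = 15,
                              paranode_periaxonal_width_nm = 0.0123,
                              nodal_gih = 0,
                              node_leak_density = 0.113,
                              leak_reversal = -84,
                              internode_leak_density = 0.001,
                              ...) {
  if (n_nodes < 1) stop("need at least one node")
  if (n_wraps < 1 && n_nodes > 1)
    stop("internodes require n_wraps >= 1")
  if (internode_length_um <= 2 * paranode_length_um && n_nodes > 1)
    stop("internode too short for its paranodal end zones")
  node_channels <- defaultChannelSet("node")
  node_channels["ih_sensitive"] <- nodal_gih
  node <- function() compartmentSpec(
    "node", node_length_um, node_diameter_um,
    channel_densities = node_channels,
    leak_density = node_leak_density, leak_reversal = leak_reversal)
  para <- function() compartmentSpec(
    "paranode", paranode_length_um, internode_diameter_um,
    n_wraps = n_wraps, periaxonal_width_nm = paranode_periaxonal_width_nm,
    channel_densities = NULL,
    leak_density = internode_leak_density, leak_reversal = leak_reversal)
  inter <- function() compartmentSpec(
    "internode", internode_length_um - 2 * paranode_length_um,
    internode_diameter_um,
    n_wraps = n_wraps, periaxonal_width_nm = periaxonal_width_nm,
    channel_densities = NULL,
    leak_density = internode_leak_density, leak_reversal = leak_reversal)
  comps <- list(node())
  if (n_nodes > 1) {
    for (i in seq_len(n_nodes - 1L)) {
      comps <- c(comps, list(para(), inter(), para(), node()))
    }
  }
  axonModel(comps, ...)
}

#' Build the truncated patch-clamped neuron model
#'
#' Soma, proximal and distal AIS, three myelinated internodes each followed by
#' a node of Ranvier, and a terminal bleb, with the three nominal 1e-7 um
#' micro-links the chain needs between soma/proximal AIS, proximal/distal AIS
#' and last node/bleb. All dimensions default to the measured specimen
#' geometry. The soma, AIS and bleb leak uses a nominal -4000 mV reversal so
#' that the leak behaves as an essentially voltage-independent (near-zero
#' conductance) current, akin to a constant pump current; its density is
#' calibrated so the unstimulated soma rests at -82 mV (see [calibrateLeak()]).
#'
#' @param gih_distal_ais adenosine-sensitive Ih density in the distal AIS,
#'   mS/mm^2 (0 = no adenosine; the measured value is 0.111)
#' @param gih_nodes adenosine-sensitive Ih density at the 3 nodes, mS/mm^2
#'   (0 = no adenosine; the nodal estimate is 0.1565)
#' @param somatic_leak_density leak density of soma/AIS/bleb, mS/mm^2, with
#'   reversal `somatic_leak_reversal`; the default is the shipped calibration
#'   for a -82 mV somatic resting potential
#' @param somatic_leak_reversal nominal leak reversal of soma/AIS/bleb, mV
#' @param node_leak_density,leak_reversal nodal leak (as in the long axon)
#' @param internode_leak_density passive internodal axolemma leak, mS/mm^2
#' @param n_wraps,periaxonal_width_nm,paranode_periaxonal_width_nm,paranode_length_um
#'   myelin geometry of the 3 internodes (as in the long axon)
#' @param n_internodes 3 by default; 0 builds a soma+AIS-only model for
#'   F-I work (the bleb then attaches directly after the distal AIS)
#' @param ... passed to [axonModel()]
#' @return an [axonModel()]
#' @export
buildPatchNeuron <- function(gih_distal_ais = 0,
                             gih_nodes = 0,
                             somatic_leak_density = 5.236e-06,
                             somatic_leak_reversal = -4000,
                             node_leak_density = 0.113,
                             leak_reversal = -84,
                             internode_leak_density = 0.001,
                             n_wraps = 5L,
                             periaxonal_width_nm = 15,
                             paranode_periaxonal_width_nm = 0.0123,
                             paranode_length_um = 1.9,
                             n_internodes = 3L,
                             ...) {
  if (!n_internodes %in% c(0L, 3L))
    stop("n_internodes must be 0 (soma+AIS only) or 3 (full chain)")
  ais_ch <- function(kind, gih) {
    cd <- defaultChannelSet(kind)
    if (kind == "distal_AIS") cd["ih_sensitive"] <- gih
    cd
  }
  node_ch <- defaultChannelSet("node")
  node_ch["ih_sensitive"] <- gih_nodes

  micro <- function(d) compartmentSpec(
    "micro_link", 1e-7, d, channel_densities = NULL,
    leak_density = somatic_leak_density,
    leak_reversal = somatic_leak_reversal)
  myel <- function(kind, L, d, w) compartmentSpec(
    kind, L, d, n_wraps = n_wraps, periaxonal_width_nm = w,
    channel_densities = NULL,
    leak_density = internode_leak_density, leak_reversal = leak_reversal)
  internode3 <- function(L, d) list(
    myel("paranode", paranode_length_um, d, paranode_periaxonal_width_nm),
    myel("internode", L - 2 * paranode_length_um, d, periaxonal_width_nm),
    myel("paranode", paranode_length_um, d, paranode_periaxonal_width_nm))
  node <- function(L, d) compartmentSpec(
    "node", L, d, channel_densities = node_ch,
    leak_density = node_leak_density, leak_reversal = leak_reversal)

  comps <- list(
    compartmentSpec("soma", 18, 18,
                    channel_densities = defaultChannelSet("soma"),
                    leak_density = somatic_leak_density,
                    leak_reversal = somatic_leak_reversal),
    micro(1.046),
    compartmentSpec("proximal_AIS", 21.9, 1.046,
                    channel_densities = ais_ch("proximal_AIS", 0),
                    leak_density = somatic_leak_density,
                    leak_reversal = somatic_leak_reversal),
    micro(0.79),
    compartmentSpec("distal_AIS", 10, 0.525,
                    channel_densities = ais_ch("distal_AIS", gih_distal_ais),
                    leak_density = somatic_leak_density,
                    leak_reversal = somatic_leak_reversal)
  )
  if (n_internodes == 3L) {
    comps <- c(comps,
               internode3(24.91, 0.51), list(node(1.126, 0.445)),
               internode3(52.44, 0.56), list(node(0.915, 0.452)),
               internode3(39.20, 0.53), list(node(0.414, 0.401)))
  }
  comps <- c(comps, list(
    micro(0.4),
    compartmentSpec("bleb", 1.64, 3,
                    channel_densities = defaultChannelSet("bleb"),
                    leak_density = somatic_leak_density,
                    leak_reversal = somatic_leak_reversal)))
  axonModel(comps, ...)
}

#' Index helpers for compartments of a given kind
#'
#' @param model an [axonModel()]
#' @param kind a compartment kind
#' @return integer vector of compartment positions in the chain
#' @export
whichCompartments <- function(model, kind) {
  which(vapply(model$compartments, function(c) c$kind, character(1)) == kind)
}

#' Midpoint position of every compartment along the chain, um
#' @param model an [axonModel()]
#' @return numeric vector of midpoint positions (um from chain start)
#' @export
compartmentPositions <- function(model) {
  L <- vapply(model$compartments, function(c) c$length_um, numeric(1))
  cumsum(L) - L / 2
}
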