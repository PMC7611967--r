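# Shared fixtures: small models built in code, plus lazily cached heavy runs
# (full-axon simulations) reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# uniform passive unmyelinated chain (no voltage-gated channels)
passiveChain <- function(n = 10, length_um = 50, diameter_um = 1,
                         leak = 0.01, e_leak = -70) {
  axonModel(lapply(seq_len(n), function(i) {
    compartmentSpec("node", length_um, diameter_um,
                    channel_densities = NULL,
                    leak_density = leak, leak_reversal = e_leak)
  }))
}

# single space-clamped node with the full excitable channel set
singleNode <- function(...) buildInfiniteAxon(n_nodes = 1L, ...)

# long-axon simulation (relaxed steady state + 1 nA / 100 us at node 1),
# recorded at all nodes; cached per nodal Ih density
infiniteRun <- function(gih, dt = 0.001, max_seg_um = 10) {
  key <- sprintf("inf_%g_%g_%g", gih, dt, max_seg_um)
  cached(key, {
    m <- buildInfiniteAxon(nodal_gih = gih)
    ss <- steadyState(m, max_seg_um = max_seg_um)
    nodes <- whichCompartments(m, "node")
    sim <- simulateAxon(m, stimulusProtocol(nodes[1], 0.05, 0.1, 1),
                        dt = dt, t_end_ms = 8, init = ss,
                        record_compartments = nodes, record_peri = FALSE)
    list(model = m, ss = ss, nodes = nodes, sim = sim)
  })
}

# truncated patch-neuron steady state, cached per (gih_dais, gih_nodes)
patchState <- function(gih_dais = 0, gih_nodes = 0) {
  key <- sprintf("patch_%g_%g", gih_dais, gih_nodes)
  cached(key, {
    m <- buildPatchNeuron(gih_distal_ais = gih_dais, gih_nodes = gih_nodes)
    list(model = m, ss = steadyState(m, max_time_ms = 6000))
  })
}
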