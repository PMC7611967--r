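test_that("g-ratio arithmetic matches the sheath geometry", {
  # 0.73 um internode, 5 wraps at 15.6 nm, 15 nm periaxonal space
  expect_equal(computeGRatio(0.73, 5, 15.6, 15),
               0.73 / (0.73 + 2 * 0.093), tolerance = 1e-12)
  expect_equal(round(computeGRatio(0.73, 5, 15.6, 15), 3), 0.797)
  # no sheath at all -> exactly 1 for any diameter/periodicity
  for (d in c(0.2, 0.73, 5)) expect_identical(computeGRatio(d, 0, 15.6, 0), 1)
  expect_error(computeGRatio(-1, 5), "> 0")
  expect_error(computeGRatio(0.73, -1), "negative")
})

test_that("g-ratio decreases strictly with wraps and periaxonal width", {
  g_w <- computeGRatio(0.73, 0:10)
  expect_true(all(diff(g_w) < 0))
  g_p <- computeGRatio(0.73, 5, periaxonal_width_nm = seq(0, 50, by = 5))
  expect_true(all(diff(g_p) < 0))
  # 5 wraps is the smallest count bringing the default internode to <= 0.8
  expect_identical(wrapsForGRatio(0.73), 5L)
  expect_gt(computeGRatio(0.73, 4), 0.8)
  expect_lte(computeGRatio(0.73, 5), 0.8)
})

test_that("the long callosal axon preset carries the printed geometry", {
  m <- buildInfiniteAxon()
  kinds <- vapply(m$compartments, function(c) c$kind, character(1))
  expect_identical(sum(kinds == "node"), 51L)
  expect_identical(sum(kinds == "internode"), 50L)
  expect_identical(sum(kinds == "paranode"), 100L)
  nodes <- m$compartments[kinds == "node"]
  expect_true(all(vapply(nodes, function(c) c$length_um, numeric(1)) == 1.5))
  expect_true(all(vapply(nodes, function(c) c$diameter_um, numeric(1)) == 0.64))
  # each 81.7 um internode = 1.9 + 77.9 + 1.9 at 0.73 um diameter
  inters <- m$compartments[kinds == "internode"]
  expect_true(all(abs(vapply(inters, function(c) c$length_um, numeric(1)) -
                        77.9) < 1e-12))
  expect_true(all(vapply(inters, function(c) c$diameter_um,
                         numeric(1)) == 0.73))
  paras <- m$compartments[kinds == "paranode"]
  expect_true(all(vapply(paras, function(c) c$periaxonal_width_nm,
                         numeric(1)) == 0.0123))
  expect_true(all(vapply(inters, function(c) c$periaxonal_width_nm,
                         numeric(1)) == 15))
  expect_equal(m$membrane_capacitance, 0.9)
  # nodal channel set
  nd <- nodes[[1]]$channel_densities
  expect_equal(unname(nd[c("naf", "nap", "ks")]), c(10, 0.01, 0.4))
  expect_equal(nodes[[1]]$leak_density, 0.113)
  expect_equal(nodes[[1]]$leak_reversal, -84)
})

test_that("degenerate single-node chain builds and is space-clamped", {
  m <- buildInfiniteAxon(n_nodes = 1)
  expect_length(m$compartments, 1L)
  sys <- assembleSystem(m)
  expect_identical(sys$nseg, 1L)
  expect_identical(sys$is_myel, 0L)
})

test_that("the truncated patch-neuron preset carries the printed geometry", {
  m <- buildPatchNeuron()
  kinds <- vapply(m$compartments, function(c) c$kind, character(1))
  getc <- function(k) m$compartments[kinds == k]
  soma <- getc("soma")[[1]]
  expect_equal(c(soma$length_um, soma$diameter_um), c(18, 18))
  dais <- getc("distal_AIS")[[1]]
  expect_equal(c(dais$length_um, dais$diameter_um), c(10, 0.525))
  pais <- getc("proximal_AIS")[[1]]
  expect_equal(c(pais$length_um, pais$diameter_um), c(21.9, 1.046))
  bleb <- getc("bleb")[[1]]
  expect_equal(c(bleb$length_um, bleb$diameter_um), c(1.64, 3))
  expect_true(all(bleb$channel_densities == 0))
  micro <- getc("micro_link")
  expect_equal(vapply(micro, function(c) c$diameter_um, numeric(1)),
               c(1.046, 0.79, 0.4))
  expect_true(all(vapply(micro, function(c) c$length_um, numeric(1)) == 1e-7))
  # three internodes at printed lengths (paranodes folded into the total)
  tot_inter <- vapply(getc("internode"), function(c) c$length_um, numeric(1)) +
    2 * 1.9
  expect_equal(tot_inter, c(24.91, 52.44, 39.20))
  nodes <- getc("node")
  expect_equal(vapply(nodes, function(c) c$length_um, numeric(1)),
               c(1.126, 0.915, 0.414))
  expect_equal(vapply(nodes, function(c) c$diameter_um, numeric(1)),
               c(0.445, 0.452, 0.401))
  # AIS adds the low-threshold Kv at 0.4 mS/mm^2
  expect_equal(unname(dais$channel_densities["klt"]), 0.4)
  expect_equal(unname(pais$channel_densities["klt"]), 0.4)
  # soma/AIS/bleb leak uses the nominal -4000 mV reversal device
  expect_equal(soma$leak_reversal, -4000)
  expect_equal(bleb$leak_reversal, -4000)
})

test_that("soma+AIS-only subchain builds and keeps chain validity", {
  m <- buildPatchNeuron(n_internodes = 0)
  kinds <- vapply(m$compartments, function(c) c$kind, character(1))
  expect_false(any(kinds %in% c("internode", "paranode", "node")))
  expect_identical(kinds[length(kinds)], "bleb")
  expect_silent(validateAxonModel(m))
})

test_that("compartment invariants are enforced", {
  expect_error(compartmentSpec("node", -1, 0.5), "length")
  expect_error(compartmentSpec("node", 1, 0), "diameter")
  expect_error(compartmentSpec("paranode", 1.9, 0.73, n_wraps = 0,
                               periaxonal_width_nm = 1), "n_wraps > 0")
  expect_error(compartmentSpec("node", 1.5, 0.64, n_wraps = 3),
               "unmyelinated")
  expect_error(compartmentSpec("internode", 70, 0.73, n_wraps = 5,
                               periaxonal_width_nm = 15,
                               channel_densities = c(naf = 1)),
               "no voltage-gated")
  # paranode periaxonal width must not exceed the adjacent internode's
  p_wide <- compartmentSpec("paranode", 1.9, 0.73, n_wraps = 5,
                            periaxonal_width_nm = 20)
  i_std <- compartmentSpec("internode", 70, 0.73, n_wraps = 5,
                           periaxonal_width_nm = 15)
  n_std <- compartmentSpec("node", 1.5, 0.64, channel_densities = NULL,
                           leak_density = 0.113)
  expect_error(axonModel(list(n_std, p_wide, i_std, p_wide, n_std)),
               "periaxonal width")
  # two internode bodies may not touch
  expect_error(axonModel(list(n_std, i_std, i_std, n_std)), "adjacent")
})

test_that("membrane areas are positive and additive over the chain", {
  m <- buildPatchNeuron()
  areas <- vapply(m$compartments, compartmentArea, numeric(1))
  expect_true(all(areas > 0))
  expect_equal(sum(areas), Reduce(`+`, lapply(m$compartments,
                                              compartmentArea)))
  # the 18 x 18 um cylindrical soma matches the area of an 18 um sphere
  expect_equal(areas[1], pi * 18^2)
})

test_that("compartment positions accumulate to chain midpoints", {
  m <- buildInfiniteAxon(n_nodes = 3)
  pos <- compartmentPositions(m)
  expect_equal(pos[1], 0.75)               # mid first node
  expect_equal(pos[length(pos)],           # mid last node
               2 * 83.2 + 1.5 - 0.75)
  expect_true(all(diff(pos) > 0))
})
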