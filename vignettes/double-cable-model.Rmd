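---
title: "The double-cable axon model and its analysis procedures"
author: "axoncable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double-cable axon model and its analysis procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoncable)
```

## The model

`axoncable` simulates action-potential conduction along myelinated axons of
layer-V cortical pyramidal neurons with a finite-impedance *double cable*:
every myelinated segment carries two potentials, the intracellular
(axonal) potential $V$ and the potential $U$ of the periaxonal space — the
nanometre-scale conducting layer between the axolemma and the innermost
myelin membrane. The axolemma (capacitance $C_m$, leak $g_L$) separates $V$
from $U$; the myelin sheath (an effective series stack of $2n$ membranes for
$n$ wraps) separates $U$ from the grounded extracellular bath. Axoplasm
couples $V$ longitudinally; the periaxonal space couples $U$ longitudinally
and opens to the bath where the myelin ends. Unmyelinated compartments
(soma, axon initial segment, nodes of Ranvier, terminal bleb) have a single
potential and carry the voltage-gated channels.

For an unmyelinated compartment $i$ the Kirchhoff balance is

$$C_i \frac{dV_i}{dt} = -\sum_c g_c(V_i)\,(V_i - E_c)
  - g_{L,i}(V_i - E_{L,i}) + \sum_{j} G_{ij}(V_j - V_i) + I_{stim},$$

and for a myelinated segment the pair

$$C_i \frac{d(V_i-U_i)}{dt} + g_{L,i}(V_i-U_i-E_{L,i})
   = \sum_j G_{ij}(V_j - V_i),$$
$$C_{my,i}\frac{dU_i}{dt} + G_{my,i}U_i
   = C_i \frac{d(V_i-U_i)}{dt} + g_{L,i}(V_i-U_i-E_{L,i})
   + \sum_j P_{ij}(U_j-U_i),$$

with $G_{ij}$ the axoplasmic and $P_{ij}$ the periaxonal coupling
conductances (reciprocal sums of half-segment resistances; $P$ couples to
the grounded bath at sheath boundaries).

### Membrane currents

Nodes of Ranvier carry a fast Na$_V$ ($m^3h$, 10 mS/mm²), a persistent
Na$_V$ ($p^3$, 0.01 mS/mm²), a slow K$_V$ ($s$, 0.4 mS/mm²), a K⁺ leak
(0.113 mS/mm², reversal −84 mV, representing nodal K2P channels such as
TRAAK) and — when adenosine/A$_{2a}$ receptor activation is modelled — an
adenosine-gated Ih. The AIS compartments add a low-threshold K$_V$
(0.4 mS/mm²). The rate equations for the Na and slow-K gates are the
published nodal kinetics of the double-cable model family this
implementation belongs to (the MRG formulation, at body temperature, no Q10
rescaling); every rate constant is exposed in `defaultKinetics()` so other
formulations from the same lineage can be substituted.

Ih is a single-gate conductance reversing at −23 mV with Boltzmann steady
state $1/(1+\exp((V-V_{1/2})/k))$, $k = 9$ mV, and a voltage-independent
activation time constant of 50 ms. Two variants exist:

* **cAMP-insensitive** (HCN1-like, somatodendritic): $V_{1/2} = -103.5$ mV,
  0.0033 mS/mm² in soma and proximal AIS — essentially deactivated at rest;
* **adenosine/cAMP-sensitive** (HCN2-like): $V_{1/2} = -80$ mV, i.e. about
  half-activated at a −82 mV resting potential. Its density is
  0.111 mS/mm² in the distal AIS and 1.41 × higher (0.1565 mS/mm²) at
  nodes, the immunohistochemically measured nodal enrichment. cAMP
  modulation is represented purely as this midpoint shift plus added
  conductance, not as a ligand-binding scheme.

The slope factor (9 mV) and time constant are not experimentally pinned;
steady-state behaviour dominates every quantity the package reports
(resting potentials, steady firing rates, propagation through quasi-steady
nodes), and the resting depolarizations change by < 10% for slopes in
7–11 mV.

### Geometries

Two presets ship (`axonPreset()`):

* **`infinite_callosal`** — a uniform axon of 51 nodes (1.5 × 0.64 µm) and
  50 internodes (81.7 × 0.73 µm). The terminal 1.9 µm of each internode is
  a paranode whose periaxonal space is nearly sealed (0.0123 nm); the
  internode body keeps a 15 nm space. With the 15.6 nm wrap periodicity,
  5 wraps give a g-ratio of ≈ 0.797 — the smallest wrap count at or below
  the physiological 0.8 (`computeGRatio()`, `wrapsForGRatio()`).
* **`patch_neuron_fig4`** — a truncated specimen neuron: an 18 × 18 µm
  cylindrical soma (the area of an 18 µm sphere), proximal AIS
  (21.9 × 1.046 µm), distal AIS (10 × 0.525 µm), three internodes
  (24.91/52.44/39.20 µm) each followed by a node, and a sealed terminal
  bleb (1.64 × 3 µm) with no voltage-gated channels. Nominal $10^{-7}$ µm
  micro-links join soma–AIS and the last node–bleb; they carry no channels
  and negligible area.

In the soma, AIS and bleb the leak reversal is a nominal −4000 mV,
converting the leak into an essentially voltage-independent current (akin
to a constant pump current) so that a resting potential of −82 mV can be
imposed without adding resting conductance; its density is calibrated by
bisection so the unstimulated soma rests at −82 mV (`calibrateLeak()`;
the shipped default is the result of that calibration,
5.236 × 10⁻⁶ mS/mm²).

### Electrical constants

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| $C_m$ | 0.9 | µF/cm² | physiologically measured membrane capacitance |
| axoplasmic resistivity | 70 | Ω·cm | model-family standard |
| periaxonal resistivity | 70 | Ω·cm | model-family standard |
| myelin periodicity | 15.6 | nm | measured wrap spacing |
| myelin capacitance / lamella membrane | 0.9 | µF/cm² | equal to $C_m$; series over $2n$ membranes |
| myelin conductance / lamella membrane | 0.01 | mS/mm² | model-family standard; series over $2n$ |
| internodal axolemma leak | 0.001 | mS/mm² | model-family standard passive axolemma |
| $E_{Na}$, $E_K$, $E_h$ | 50, −84, −23 | mV | $E_K$ equals the nodal leak reversal |

Sheath capacitance and conductance are evaluated at the mid-sheath
circumference (the first-order equivalent of the series stack of concentric
lamellae). All constants are fields of `axonModel()` and serialize to the
YAML config dialect (`writeModelConfig()`/`readModelConfig()`, round-trip
exact).

## Numerics

Long myelinated compartments are subdivided into ≤ 10 µm sub-segments;
excitable compartments (soma, AIS, nodes, bleb, micro-links) are single
isopotential units, the discretization convention of the model family
(keeping the AIS isopotential matters: subdividing it into active
sub-segments makes backward soma invasion several-fold faster).
Compartment-level outputs are reported at the compartment's midpoint
sub-segment.

The system is stiff — the paranodal periaxonal space is 0.0123 nm wide —
so voltages advance by backward Euler on a pentadiagonal linear system
(states interleaved along the chain), with gates advanced by exponential
Euler at the pre-step voltage. Defaults: `dt = 1 µs` for conduction-speed
measurements, 25 µs for 1-s firing-rate runs. Halving both `dt` and the
sub-segment length changes the measured conduction speed by < 0.2% (the
refinement test asserts < 1%), and the passive steady-state profile matches
the sealed-end analytic cable solution to < 1%.

Resting states are found by implicit relaxation (0.5 ms steps until
max |dV/dt| < 10⁻⁶ mV/ms, at least 2 s simulated — the 50 ms Ih gate needs
it), which is deterministic and seed-free; a model that keeps moving after
10 s raises an error naming spontaneous firing rather than averaging over
an oscillation. Spike arrival times use the maximum-dV/dt convention with
parabolic sub-sample interpolation; a −20 mV threshold-crossing alternative
agrees within one time step on the default models. Firing rates count
upward −50 mV crossings with a 1 ms refractory guard.

## Virtual experiments

* `calibrateLeak()` — log-scale bisection of a leak density to a target
  resting potential; reports degeneracy when the target equals the
  reversal, and the achievable range when the target is not bracketable.
* `fiCurve()` — 1-s current steps at the soma, rate = −50 mV crossings/s.
* `sweepGih()` — steady-state soma depolarization, node resting potential
  and (optionally) first-to-last-node speed over a grid of
  adenosine-sensitive Ih densities (default 0–0.2 mS/mm² in 0.02 steps,
  the range over which the resting and speed effects saturate), placed in
  the distal AIS or at the nodes.
* `conductionSpeed()`, `spikeWidthChange()` — chain-distance/arrival-time
  speeds and the change in nodal spike full width at half-maximum
  (baseline = that condition's resting potential).

## Analysis procedures

* `extractTailAmplitude()` — single-exponential fit (Levenberg–Marquardt)
  to a tail current after a configurable 1 ms capacitive-blanking window,
  extrapolated back to the end of the pre-pulse. Time constants outside
  (0.5 ms, 5 s) or failed fits are flagged and fall back to the window
  mean.
* `fitActivation()` — four-parameter Boltzmann fit
  $I = I_{max} + (I_{min}-I_{max})/(1+\exp(k(V-V_{1/2})))$ of tail
  amplitude versus pre-pulse voltage ($k > 0$: activation grows with
  hyperpolarization; all four parameters free), and
  $G_{max} = (I_{max}-I_{min})/(V_{rev}-V_{tail})$ with
  $V_{rev} = -23$ mV, $V_{tail} = -136$ mV.
* `measureLatency()` — per-sweep first derivatives, alignment on the
  somatic derivative peak, averaging, then onsets as the last sample before
  the averaged somatic dV/dt exceeds +1 mV/ms and the averaged bleb dI/dt
  falls below −0.5 pA/ms. Because these thresholds sit near 0.1% of the
  events' peak derivatives, the slope is estimated over a 0.2 ms central
  base (matched to recording bandwidth; identical for both channels so the
  shift cancels), and the crossing is taken at the start of the contiguous
  suprathreshold run ending at the derivative extremum, which ignores
  isolated noise crossings.
* `estimateVelocity()` — converts a latency $T$ into a speed under one of
  two explicit initiation-site conventions, never a silent default:
  $v = (x_{bleb} - 2x_{soma})/T$ (initiation mid-AIS, forward speed twice
  backward) or $v = (x_{bleb} - 3x_{soma})/T$ (initiation at the AIS end,
  3 × ratio).
* `spikeWidthFwhm()` — full width at half of peak-minus-baseline
  (pre-spike median or an explicit baseline), sub-sample by linear
  interpolation, with a 5 × baseline-noise peak guard; `polarity = "down"`
  for inward-current events.

## Synthetic data

The generators build every input the analyzers need, with the ground truth
echoed into the returned object, and are pure functions of their arguments
(a private Mersenne-Twister stream; the caller's RNG state is untouched):

* `genTailFamily()` — tail-current families over the −56…−146 mV pre-pulse
  grid, amplitudes on a Boltzmann curve, single-exponential tails plus
  white Gaussian noise.
* `genDualRecording()` — paired soma-voltage/bleb-current sweeps with a
  known onset latency, per-sweep timing jitter and band-limited noise. The
  somatic spike is a raised-cosine upstroke with exponential
  repolarization, identically zero before its onset; the bleb "action
  current" is the scaled negative *closed-form* derivative of such a
  waveform — the simplest physically motivated stand-in for a
  cell-attached capacitive current, and a modelling choice rather than a
  claim about the pipette. (A discrete derivative would leak the onset one
  sample early and bias every latency estimate.)
* `genSpikeTrace()` — single Gaussian or biphasic events of exactly known
  width for width-measurement validation.

Noise in the dual recording is white Gaussian low-pass filtered to 0.25 ms
(recordings are hardware-filtered far below the sampling rate), with
default RMS amplitudes of 0.02 mV / 0.02 pA emulating clean averaged-grade
channels. This matters: the ±1 mV/ms and −0.5 pA/ms onset thresholds
tolerate only ~0.2 pA/ms of noise in the averaged derivative, so realistic
single-sweep noise demands the ≥ 100-sweep averaging the experimental
procedure actually uses; with the shipped defaults the latency property
(bias below one 20 µs sample over jitter 0–40 µs and 10–100 sweeps) holds.

What the synthetic data do *not* emulate: electrode series resistance and
capacitance artifacts, liquid-junction offsets (a −16 mV correction is
applied upstream in experiments), multi-spike sweeps, drifting baselines,
and correlated (non-Gaussian) noise. Passing the recovery tests therefore
demonstrates the correctness of the estimators under their stated model,
not robustness to every pathology of real recordings.

## Calibrations and known limitations

Two calibrations anchor the models: the somatic leak of the truncated
neuron is bisected so the soma rests at −82 mV (shipped default above),
and the nodal leak of 0.113 mS/mm² at −84 mV is intended to rest the nodes
at −82 mV. With the shipped gating kinetics the second anchor is imperfect:
the fast-Na window current at −82 mV is ~40% smaller than that anchor
requires, so the node rests near −83.2 mV and `calibrateLeak()` returns
~0.036 mS/mm² for a −82 mV target. A 2.4 mV hyperpolarizing shift of the
Na activation curve restores the anchor but makes the nodal-Ih-depolarized
axon (resting near −70 mV) fire spontaneously, so the unmodified lineage
kinetics are shipped and the residual offset documented rather than hidden.

More generally, the quantities most sensitive to the gating kinetics are
the split of the per-node conduction delay between node charging and
internodal cable delay, and the safety margin of conduction. With the
shipped kinetics the internodal cable delay dominates, so the truncated
model's short internodes conduct at ~3.4 m/s forward (rather than scaling
down proportionally to internode length), backward soma invasion is fast
(~1.9 m/s), adding nodal Ih slows the long axon by ~12% (2.50 → 2.21 m/s)
while depolarizing nodes by +13.1 mV, and the propagating spike *narrows*
slightly on depolarization instead of widening (halving the peak Na
conductance widens it by only ~0.02 ms; a four-fold reduction is needed
for ~0.2 ms of widening and approaches propagation failure). Kinetic
formulations with less Na availability at rest move all of these toward
stronger Ih effects and slower truncated-model speeds at the same printed
densities and geometry. Firing-rate effects of distal-AIS Ih show the
expected direction at low-to-mid currents (e.g. 7 → 13 Hz at 100 pA) but
no high-current rate suppression at 180 pA, because the simulated
spike-amplitude depression does not reach the −50 mV counting criterion
with these kinetics.

Problem sizes used throughout the tests: the 51-node axon discretizes to
551 segments (1051 states) and simulates 8 ms at 1 µs steps in about a
second; the truncated neuron is 28 segments; firing-rate runs use 1-s
steps at 25 µs. These keep the full test suite around a minute.

## Worked example

```{r example, eval = FALSE}
m0 <- buildInfiniteAxon() # no adenosine
mih <- buildInfiniteAxon(nodal_gih = 0.1565) # A2a receptors active
nodes <- whichCompartments(m0, "node")
run <- function(m) {
  ss <- steadyState(m)
  sim <- simulateAxon(m, stimulusProtocol(nodes[1], 0.05, 0.1, 1),
                      dt = 0.001, t_end_ms = 8, init = ss,
                      record_compartments = nodes)
  c(rest = ss$V[nodes[26]],
    speed = conductionSpeed(m, sim, nodes[21], nodes[31]))
}
rbind(control = run(m0), adenosine = run(mih))
#>             rest    speed
#> control   -83.19 2.50
#> adenosine -70.06 2.21
```
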