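Package: axoncable
Title: Double-Cable Modelling of Myelinated Axons and Adenosine-Modulated Ih
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates action-potential conduction along myelinated axons with
    a finite-impedance double-cable (axonal plus periaxonal) compartmental
    model, including Hodgkin-Huxley style nodal channels and the
    hyperpolarization-activated current Ih with and without cAMP/adenosine
    modulation of its activation midpoint. Ships two reference geometries
    (an effectively infinite callosal axon of 51 nodes and a truncated
    soma-AIS-3-internode-bleb neuron), virtual-experiment drivers (leak
    calibration, resting-potential shifts, F-I curves, conductance sweeps,
    conduction-speed and spike-width measurement), analysis routines for
    voltage-clamp tail currents (single-exponential extrapolation, Boltzmann
    activation fits, maximal conductance), derivative-threshold soma-to-bleb
    latency measurement and latency-to-velocity conversion, and seeded
    synthetic-data generators for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
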