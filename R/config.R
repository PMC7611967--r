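#' Serialize an axon model to a flat, human-editable config file
#'
#' The config dialect is YAML with two blocks: `constants` (the global
#' electrical parameters and the gating-rate table) and `compartments` (one
#' entry per compartment with geometry, wraps, periaxonal width, channel
#' densities and leak). Reading the file back reproduces an identical chain.
#'
#' @param model an [axonModel()]
#' @param path output path (`.yaml`)
#' @return `path`, invisibly
#' @export
writeModelConfig <- function(model, path) {
  comps <- lapply(model$compartments, function(cp) {
    list(kind = cp$kind,
         length_um = cp$length_um,
         diameter_um = cp$diameter_um,
         n_wraps = cp$n_wraps,
         periaxonal_width_nm = cp$periaxonal_width_nm,
         channel_densities = as.list(cp$channel_densities),
         leak_density = cp$leak_density,
         leak_reversal = cp$leak_reversal)
  })
  cfg <- list(
    constants = list(
      membrane_capacitance = model$membrane_capacitance,
      myelin_periodicity = model$myelin_periodicity,
      axial_resistivity = model$axial_resistivity,
      periaxonal_resistivity = model$periaxonal_resistivity,
      myelin_capacitance_per_lamella = model$myelin_capacitance_per_lamella,
      myelin_conductance_per_lamella = model$myelin_conductance_per_lamella,
      kinetics = model$kinetics),
    compartments = comps)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  comps <- lapply(cfg$compartments, function(cp) {
    compartmentSpec(cp$kind, cp$length_um, cp$diameter_um,
                    n_wraps = cp$n_wraps,
                    periaxonal_width_nm = cp$periaxonal_width_nm,
                    channel_densities = unlist(cp$channel_densities),
                    leak_density = cp$leak_density,
                    leak_reversal = cp$leak_reversal)
  })
  k <- cfg$constants
  axonModel(comps,
            membrane_capacitance = k$membrane_capacitance,
            myelin_periodicity = k$myelin_periodicity,
            axial_resistivity = k$axial_resistivity,
            periaxonal_resistivity = k$periaxonal_resistivity,
            myelin_capacitance_per_lamella = k$myelin_capacitance_per_lamella,
            myelin_conductance_per_lamella = k$myelin_conductance_per_lamella,
            kinetics = k$kinetics)
}

#' Named model presets
#'
#' `"infinite_callosal"`: the uniform 51-node / 50-internode callosal axon
#' ([buildInfiniteAxon()]). `"patch_neuron_fig4"`: the truncated
#' soma-AIS-3-internode-bleb specimen neuron ([buildPatchNeuron()]).
#'
#' @param name preset name
#' @param ... overrides passed to the underlying builder
#' @return an [axonModel()]
#' @export
axonPreset <- function(name = c("infinite_callosal", "patch_neuron_fig4"),
                       ...) {
  name <- match.arg(name)
  switch(name,
         infinite_callosal = buildInfiniteAxon(...),
         patch_neuron_fig4 = buildPatchNeuron(...))
}
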