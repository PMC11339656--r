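# Shared fixtures built in code.

fixture_path <- function(name) {
  system.file("extdata", name, package = "mipgreen", mustWork = TRUE)
}

# a minimal valid raw procedure list, ready to perturb in schema tests
minimal_raw_procedure <- function() {
  list(
    schema_version = 1,
    inhibitor_removal = "not_needed_or_no_waste",
    substances = list(
      functional_monomer = list(
        list(name = "monomer", amount = 1, unit = "g", codes = list("H225")))),
    initiation = "uv_mediated",
    particle_size = "nm_100_to_1000",
    elution_solvents = list(list(name = "water")),
    elution_technique = "mixing_or_shaking",
    reuse_cycles = 5)
}

tiny_table <- function() {
  penalty_table(c("H225", "H301", "H315"), c(6, 8, 2), source_label = "test")
}
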