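# Synthesis-procedure description for greenness assessment (schema version 1).
# Fill in each field; delete optional blocks you do not need.
schema_version: 1
metadata:
  title: "My MIP synthesis"          # optional
  reference: "doi or citation"       # optional
  notes: ""                          # optional

# Criterion 1 - removal of polymerization inhibitors. One of:
#   not_needed_or_no_waste | solid_waste | liquid_waste | solid_and_liquid_waste
inhibitor_removal: not_needed_or_no_waste

# Criteria 2-7 - reagents by synthesis role. Roles:
#   functional_monomer (criterion 2), template (3), cross_linker (4),
#   porogen (5), other_reagent (6), core_surface (7).
# Each entry: name, amount, unit (g | mg | mL), optional density (g/mL,
# needed for mL amounts of solvents not in the packaged density table),
# optional cas, and the reagent's GHS H-codes. Omit a role entirely if the
# stage does not exist in the procedure.
substances:
  functional_monomer:
    - name: methacrylic acid
      cas: "79-41-4"
      amount: 0.86
      unit: g
      codes: [H226, H302, H311, H314, H335]
  template:
    - name: example template
      amount: 50
      unit: mg
      codes: [H302]
  cross_linker:
    - name: ethylene glycol dimethacrylate
      amount: 2.0
      unit: g
      codes: [H315, H317, H319, H335]
  porogen:
    - name: acetonitrile
      amount: 10
      unit: mL
      codes: [H225, H302, H312, H319, H332]

# Criterion 8 - polymerization initiation. One of:
#   heating_mixing_only | mixing_with_initiator | heating_mixing_with_initiator |
#   sonication_or_microwave | uv_mediated | electropolymerization |
#   self_polymerization
initiation: heating_mixing_with_initiator

# Criterion 9 - particle size. One of:
#   macro_extraction_device | above_1000nm | nm_100_to_1000 |
#   micrometer_crushed_sieved | nm_10_to_100 | carbon_dots | quantum_dots
particle_size: micrometer_crushed_sieved

# Criterion 10 - template elution solvent(s); only hazards count, volumes are
# not part of this criterion. H-codes of all listed solvents are pooled.
elution_solvents:
  - name: methanol
    codes: [H225, H301, H311, H331, H370]

# Criterion 11 - elution technique. One of:
#   soxhlet | mixing_or_shaking | supercritical_fluid | ultrasound_or_microwave
elution_technique: mixing_or_shaking

# Criterion 12 - usable sorption-desorption cycles (positive integer).
reuse_cycles: 5

# Optional: override the default weights (12 integers, 1-4) and justify.
# weights: [1, 2, 1, 3, 4, 3, 2, 3, 1, 4, 3, 3]
# weights_justification: ""

# Optional: path to a custom hazard-penalty table (CSV 'code,points' or YAML).
# penalty_table: my_penalties.csv
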