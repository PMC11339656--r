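# Approximate - for illustration. Loosely modeled on a dual-template
# surface-imprinted polymer on silica gel consuming large toluene volumes as
# solvent and porogen, with HCl, pyridine, and acryloyl chloride used during
# silica modification. Amounts and hazard sets are plausible stand-ins for
# the original inventory; penalty sums depend on the packaged synthetic
# penalty table.
schema_version: 1
metadata:
  title: "Dual-template surface MIP on silica gel (approximate)"
  notes: "approximate - for illustration"
inhibitor_removal: liquid_waste
substances:
  functional_monomer:
    - name: methacrylic acid
      cas: "79-41-4"
      amount: 1.7
      unit: g
      codes: [H226, H302, H311, H314, H335]
  template:
    - name: imidacloprid
      amount: 0.26
      unit: g
      codes: [H302, H410]
    - name: acetamiprid
      amount: 0.22
      unit: g
      codes: [H302, H410]
  cross_linker:
    - name: ethylene glycol dimethacrylate
      amount: 4.0
      unit: g
      codes: [H315, H317, H319, H335]
  porogen:
    - name: toluene
      cas: "108-88-3"
      amount: 60
      unit: mL
      codes: [H225, H304, H315, H336, H361, H373]
  other_reagent:
    - name: hydrochloric acid solution
      amount: 50
      unit: g
      codes: [H290, H314, H335]
    - name: pyridine
      amount: 20
      unit: mL
      codes: [H225, H302, H312, H332]
  core_surface:
    - name: toluene (silica modification washes)
      amount: 120
      unit: mL
      density: 0.867
      codes: [H225, H304, H315, H336, H361, H373]
    - name: acryloyl chloride
      amount: 5
      unit: g
      codes: [H225, H301, H311, H314, H331]
initiation: heating_mixing_with_initiator
particle_size: micrometer_crushed_sieved
elution_solvents:
  - name: methanol
    codes: [H225, H301, H311, H331, H370]
  - name: acetic acid
    codes: [H226, H314]
elution_technique: soxhlet
reuse_cycles: 3
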