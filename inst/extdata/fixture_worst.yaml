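# Idealized all-worst procedure: every criterion at its minimum score.
schema_version: 1
metadata:
  title: "Idealized worst-case MIP synthesis"
  notes: "synthetic fixture - every criterion at its printed minimum"
inhibitor_removal: solid_and_liquid_waste
substances:
  functional_monomer:
    - name: bulk toxic monomer
      amount: 500
      unit: g
      codes: [H300, H310, H330]
  template:
    - name: bulk toxic template
      amount: 500
      unit: g
      codes: [H300, H340]
  cross_linker:
    - name: bulk toxic cross-linker
      amount: 500
      unit: g
      codes: [H310, H314]
  porogen:
    - name: bulk chlorinated porogen
      amount: 2000
      unit: g
      codes: [H301, H331, H351, H410]
  other_reagent:
    - name: bulk corrosive adjuvant
      amount: 1000
      unit: g
      codes: [H314, H330]
  core_surface:
    - name: bulk surface-modification bath
      amount: 1000
      unit: g
      codes: [H310, H372]
initiation: heating_mixing_only
particle_size: quantum_dots
elution_solvents:
  - name: highly hazardous solvent blend
    codes: [H300, H310, H330, H340]
elution_technique: soxhlet
reuse_cycles: 1
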