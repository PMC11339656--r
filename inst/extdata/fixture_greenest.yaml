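# Idealized all-greenest procedure: every criterion at its maximum score.
schema_version: 1
metadata:
  title: "Idealized greenest MIP synthesis"
  notes: "synthetic fixture - every criterion at its printed maximum"
inhibitor_removal: not_needed_or_no_waste
substances:
  functional_monomer:
    - name: hazard-free biomonomer
      amount: 0.1
      unit: g
      codes: []
  template:
    - name: hazard-free template
      amount: 10
      unit: mg
      codes: []
initiation: self_polymerization
particle_size: macro_extraction_device
elution_solvents:
  - name: water
    codes: []
elution_technique: ultrasound_or_microwave
reuse_cycles: 12
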