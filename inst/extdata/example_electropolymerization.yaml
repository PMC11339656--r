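# Approximate - for illustration. Loosely modeled on an electrochemically
# synthesized imprinted polypyrrole film for SPME (cyclic-voltammetry
# electropolymerization, ~4 mL acetonitrile porogen, ~5 mmol sulfadimethoxine
# template). The full reagent inventory lives in the original synthesis
# report; amounts and hazard sets here are plausible stand-ins, and penalty
# sums depend on the packaged synthetic penalty table.
schema_version: 1
metadata:
  title: "Electropolymerized film MIP for SPME (approximate)"
  notes: "approximate - for illustration"
inhibitor_removal: not_needed_or_no_waste
substances:
  functional_monomer:
    - name: pyrrole
      cas: "109-97-7"
      amount: 0.27
      unit: g
      codes: [H226, H302, H311, H331]
  template:
    - name: sulfadimethoxine
      cas: "122-11-2"
      amount: 1.55
      unit: g
      codes: [H315, H319, H335]
  cross_linker:
    - name: ethylene glycol dimethacrylate
      cas: "97-90-5"
      amount: 0.4
      unit: g
      codes: [H315, H317, H319, H335]
  porogen:
    - name: acetonitrile
      cas: "75-05-8"
      amount: 4
      unit: mL
      codes: [H225, H302, H312, H319, H332]
initiation: electropolymerization
particle_size: macro_extraction_device
elution_solvents:
  - name: methanol
    codes: [H225, H301, H311, H331, H370]
elution_technique: mixing_or_shaking
reuse_cycles: 10
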