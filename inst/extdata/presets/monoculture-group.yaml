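# M-only group selection, single-cell founders, excess Byproduct
monoculture: true
strategy: top_dog
n_tot: 100
n_cycles: 500
mut:
  mutable: [fP]
reproduction:
  method: pipetting
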