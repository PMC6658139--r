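# H may evolve to outgrow M (gHmax bound 0.8 > gMmax bound 0.7); more Resource
strategy: top_dog
n_tot: 100
n_cycles: 2000
R0: 10
params:
  set: ancestral
  gHmax_bound: 0.8
mut:
  mutable: [gHmax, affHR, gMmax, affMR, affMB, fP]
reproduction:
  method: pipetting
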