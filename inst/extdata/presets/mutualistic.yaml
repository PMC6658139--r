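# Byproduct inhibits H (B0 = 2 K_MB); longer maturation
strategy: top_dog
n_tot: 100
n_cycles: 1000
T: 20
params:
  B0: 66.666666666666671
reproduction:
  method: pipetting
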