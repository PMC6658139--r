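# T = 20: Resource nearly depleted by the end of maturation (stationary phase)
strategy: top_dog
n_tot: 100
n_cycles: 1000
T: 20
reproduction:
  method: pipetting
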