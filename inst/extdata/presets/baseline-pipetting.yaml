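# top-dog choice, reproduction by pipetting, only fP mutable (baseline regimen)
strategy: top_dog
n_tot: 100
n_cycles: 1000
T: 17
reproduction:
  method: pipetting
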