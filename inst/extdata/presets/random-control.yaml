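# no intercommunity selection: Adults chosen at random
strategy: random_control
n_tot: 100
n_cycles: 500
reproduction:
  method: pipetting
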