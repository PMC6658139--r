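# top 10% of Adults each contribute n_tot/n_chosen Newborns, via pipetting
strategy: top_tier
n_chosen: 10
n_tot: 100
n_cycles: 1000
reproduction:
  method: pipetting
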