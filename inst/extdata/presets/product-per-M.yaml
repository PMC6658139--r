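# alternative community function P(T)/M(T): drives fP up until M crashes
strategy: top_dog
function_def: product_per_M
n_tot: 100
n_cycles: 300
reproduction:
  method: pipetting
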