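# fixed 100-fold dilution with excess Resource: selects big Newborns, not fP
strategy: top_dog
n_tot: 100
n_cycles: 30
R0: 10
reproduction:
  method: fixed_fold
  fixed_fold_nD: 100
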