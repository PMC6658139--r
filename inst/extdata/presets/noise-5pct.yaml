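# community-function measurement noise, sd = 5% of ancestral P(T)
strategy: top_dog
noise_sd_frac: 0.05
n_tot: 100
n_cycles: 1000
reproduction:
  method: sort_biomass
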