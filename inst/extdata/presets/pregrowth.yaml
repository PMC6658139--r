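# first-cycle M cells drawn from a pregrown founder monoculture (~3% nulls)
strategy: top_dog
pregrowth: true
pregrowth_shared_pool: true
n_tot: 100
n_cycles: 1000
reproduction:
  method: sort_biomass
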