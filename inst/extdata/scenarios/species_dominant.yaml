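# No shared tissue signal; variation comes from species offsets alone.
# Cross-species transfer should perform at chance.
n_genes: 40
tissues: [brain, heart, kidney]
species: [Homo, Gallus]
samples_per_cell:
  Homo: 10
  Gallus: 4
tissue_sd: 0.0
species_sd: 1.0
noise_sd: 0.25
missing_rate: 0.0
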