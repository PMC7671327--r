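# Tissue signal dominates species offsets: cross-species transfer of the
# tissue classifier should succeed well above chance.
n_genes: 40
tissues: [brain, heart, kidney]
species: [Homo, Gallus]
samples_per_cell:
  Homo: 10
  Gallus: 4
tissue_sd: 1.0
species_sd: 0.5
noise_sd: 0.25
missing_rate: 0.0
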