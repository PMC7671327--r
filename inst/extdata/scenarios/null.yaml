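# Labels carry no signal at all: features are baseline + noise only.
# Used for classifier calibration (accuracy should sit at 1/K).
n_genes: 20
tissues: [brain, heart, kidney]
species: [Homo]
samples_per_cell:
  Homo: 20
tissue_sd: 0.0
species_sd: 0.0
noise_sd: 0.25
missing_rate: 0.0
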