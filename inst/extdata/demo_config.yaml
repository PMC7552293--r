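# Demo configuration for run_pipeline(): a seven-breed cohort with a
# low-frequency deletion, a 50-animal pilot, pool sizes 3-20, a 276-animal
# two-locus LD subsample, and an eight-trait association panel.
seed: 20200821
population:
  breed_sizes: {TS: 907, LXBH: 629, STHS: 190, LFTS: 49, HS: 201, SS: 48, AUW: 326}
  maf: {TS: 0.007, LXBH: 0.011, STHS: 0.008, LFTS: 0.010, HS: 0, SS: 0, AUW: 0}
  sex_counts:
    TS: [458, 449]
design:
  n_pilot: 50
  a_min: 3
  a_max: 20
ld:
  breed: TS
  n: 276
  partner_maf: [0.05, 0.08]
  d_prime: 0.3
association:
  breed: TS
  genotype_effect: {BL: -3.6, CD: -1.9, CW: 1.7}
  noise_family: skewed
  alpha: 0.05
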