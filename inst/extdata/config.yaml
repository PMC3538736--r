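# Full-defaults pipeline configuration template. Any field may be omitted;
# missing values fall back to these defaults (see ?run_config).
seed: 1
phantom:
  grid_shape: [128, 128]
  f_cortex_left: 316     # ml/100 g/min, diseased side
  f_cortex_right: 416    # ml/100 g/min, healthy side
  f_medulla: 150
  m0_tissue: 100         # arbitrary units
  t1_tissue: 1.14        # s
  noise_sigma: 0.3       # additive Gaussian frame noise, arbitrary units
asl:
  ti: 1.2                # inflow (inversion) time, s
  t1: 1.14               # tissue T1 used for quantification, s
  lambda: 0.8            # blood-tissue partition coefficient, ml/g
  n_pairs: 30            # tag/control pairs (series has 3*n_pairs frames)
dce:
  dt: 0.9                # volume spacing, s
  n_baseline: 15         # pre-contrast volumes
  n_volumes: 50
  first_pass_volumes: 50 # 60 for slower boluses
  threshold_fraction: 0.15  # truncated-SVD cutoff for noisy data
  n_slices: 3
stats:
  ddof_groups: 1         # sample SD for group summaries
  ddof_diffs: 0          # population SD for difference/repeat summaries
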