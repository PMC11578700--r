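# Example pipeline configuration.
# input_dir: /path/to/faers/quarter     # omit to run on the synthetic fixture
# out_dir: results/run1
levels: [smq, soc, pt]
counting: event
year_field: fda_dt
synth: fixture_scaled
seed: 1
criteria:
  min_count: 3
  ror_ci_low: 1
  prr_min: 2
  chi2_min: 4
  ic025_min: 0
  ebgm05_min: 2
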