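# Demo pipeline configuration: synthetic microdata for four countries,
# chronic-morbidity and self-rated-health schemes, full validation battery.
# Set out_dir (or override it programmatically) before running.
out_dir: wahe_demo_output
seed: 42
simulate:
  countries: [AA, BB, CC, DD]
  n_per_stratum: 2000
schemes: [chronic, srh, multi]
age_anchor: 15
alpha: 0.05
min_cell: 30
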