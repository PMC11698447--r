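# Default run configuration. Any omitted block or field keeps the
# package default; see ?run_config for the constructors behind each block.
cohort:
  birth_year_from: 1890
  birth_year_to: 1984
  births_per_year: 1000
  scale: 1.0
policy:
  start_age: 55
  end_age: 77
  min_pack_years: 30
  max_quit_years: 15
  screens_per_year: 1
run:
  scenario: baseline_symptomatic
  window: [1979, 1999]
  ct_unit_cost: 3074
  seed: 1
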