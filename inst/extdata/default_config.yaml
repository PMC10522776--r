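# Default pipeline configuration: a small synthetic study that exercises
# every stage end to end in a couple of minutes.
seed: 1
srb: 1.05
simulation:
  n_countries: 12
  years: [1995, 2014]
  age_groups: ["0-4"]
  rho_truth: 0.9
  tau_truth: 0.1
  obs_per_country_year: 1
model:
  n_knots: 5
  n_draws: 400
  n_warmup: 300
validation:
  fraction: 0.2
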