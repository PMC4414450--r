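scenario:
  reported_assaults_per_year: 635.0
  pct_outdoors: 0.3
  pct_reported: 0.15
  pct_enroute: 0.5
  female_prop: 0.52
  household_size: 4.0
  families_per_toilet: 17.5
  trips_per_day: 6.0
  walk_speed_kph: 5.0
  toilet_cost_rand: 10315.0
  fx_rand_per_usd: 9.9
  assault_cost_usd: 53000.0
  cluster_size: 7.0
  baseline_toilets: 5600.0
  days_per_year: 365.0
  base_roundtrip_m: 210.0
  effective_area_km2: 35.28
ranges:
- name: pct_outdoors
  low: 0.2
  base: 0.3
  high: 0.4
- name: pct_reported
  low: 0.05
  base: 0.15
  high: 0.25
- name: pct_enroute
  low: 0.2
  base: 0.5
  high: 0.8
- name: female_prop
  low: 0.5
  base: 0.52
  high: 0.54
- name: trips_per_day
  low: 2.0
  base: 6.0
  high: 10.0
- name: walk_speed_kph
  low: 3.0
  base: 5.0
  high: 7.0
- name: toilet_cost_usd
  low: 521.0
  base: 1042.0
  high: 1563.0
- name: assault_cost_usd
  low: 26500.0
  base: 53000.0
  high: 79500.0
- name: cluster_size
  low: 1.0
  base: 7.0
  high: 13.0
psa:
  n_draws: 5000.0
  seed: 1
simulation:
  n_sal: 583.0
  n_samples: 100000.0
  boundary_mode: bounded
  seed: 1
rounded: yes
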