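seed: 7
species:
  - species_id: Early_mover
    mean_doy_at_ref: 90
    drift_days_per_decade: -2
    kappa: 15
    records_per_year_rate: 1.2
    year_range: [1940, 2000]
  - species_id: Stable_bloomer
    mean_doy_at_ref: 180
    drift_days_per_decade: 0
    kappa: 20
    records_per_year_rate: 1.2
    year_range: [1940, 2000]
  - species_id: Late_mover
    mean_doy_at_ref: 250
    drift_days_per_decade: 3
    kappa: 15
    records_per_year_rate: 1.2
    year_range: [1940, 2000]
  - species_id: Yearwrap_bloomer
    mean_doy_at_ref: 360
    drift_days_per_decade: 2
    kappa: 10
    records_per_year_rate: 1.5
    year_range: [1930, 2000]
    effort_dip:
      start_year: 1930
      end_year: 1945
      multiplier: 0.5
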