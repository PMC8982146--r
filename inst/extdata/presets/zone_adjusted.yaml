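name: zone_adjusted
controller:
  np: 9
  nu: 5
  zone_day:
  - 80.0
  - 110.0
  zone_night:
  - 80.0
  - 100.0
  zone_window:
  - 360.0
  - 1320.0
  delivery_window:
  - 360.0
  - 1320.0
  gref: 90.0
  vel_band:
  - 140.0
  - 180.0
  D: 10.0
  r_plus: 6500.0
  r_minus: 100.0
  q_high: 500.0
  q_vel_thresh: 1.0
  lambda_hours: 4.0
  mu_breaks:
  - 120.0
  - 180.0
  mu_hours:
  - 6.0
  - 4.0
  - 2.0
  curve_shape: linear
  name: zone_adjusted
bolus:
  gm: 120.0
  alpha: 0.80000000000000004
  tau_c: 150.0
  gref_corr: 150.0
  cap: 2.0
  delta_min: 120.0

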