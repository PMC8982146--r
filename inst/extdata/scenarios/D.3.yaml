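id: D.3
dvmx: -0.67000000000000004
dkp3: -0.67000000000000004
g0: ~
basal_mode: scaled
basal_scale: 1.5
cr_scale: 1.0
cf_scale: 0.67000000000000004
meals:
  times:
  - 480.0
  - 780.0
  - 1140.0
  grams:
  - 40.0
  - 40.0
  - 40.0
  advance_bolus: 0.0
  first_meal_delay: 0.0

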