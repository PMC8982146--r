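id: D.1
dvmx: 0.25
dkp3: 0.25
g0: 60.0
basal_mode: b90
basal_scale: 1.0
cr_scale: 0.90000000000000002
cf_scale: 0.90000000000000002
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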