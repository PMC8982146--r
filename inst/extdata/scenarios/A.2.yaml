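id: A.2
dvmx: 0.0
dkp3: 0.0
g0: 90.0
basal_mode: b90
basal_scale: 1.0
cr_scale: 1.0
cf_scale: 1.0
meals:
  times:
  - 480.0
  - 780.0
  - 1140.0
  grams:
  - 40.0
  - 40.0
  - 40.0
  advance_bolus: 30.0
  first_meal_delay: 0.0

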