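id: B.3.a
dvmx: 0.0
dkp3: 0.0
g0: 60.0
basal_mode: nominal
basal_scale: 1.0
cr_scale: 1.10000000000000009
cf_scale: 1.10000000000000009
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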