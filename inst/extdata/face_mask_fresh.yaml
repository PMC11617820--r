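# 8-h wear of an AgCur-coated face mask on fresh (healthy) skin.
# Family-average areal load and abrasion release constant; stratum-corneum
# constant from the fresh human skin graft diffusion-cell measurement.
product:
  load_ng_cm2: 1530
  area_cm2: 555
  fa: 1
rates:
  kp_per_min: 0.086
  ksc_per_h: 1.8e-6
  ko_per_min: 0
  kww_per_min: 0
schedule:
  horizon_h: 8
  wear_h: 8
subject:
  bw_kg: 60
  dnel_mg_kg_day: 0.01
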