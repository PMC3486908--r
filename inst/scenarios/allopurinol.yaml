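# Xanthine-oxidase inhibition therapy of hyperuricemia: defaults.
scenario: allopurinol
dose_mg: 200
n_doses: 35               # once daily over 35 days
dose_interval: 1440
inhibition:
  allopurinol_ic50_uM: 13.4
  oxypurinol_ic50_uM: 15.6
calibration:
  gouty_venous_uM: 476
  healthy_venous_uM: 302
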