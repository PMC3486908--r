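# Urea-cycle-disorder pathogenesis (hyperammonemia) scenario defaults.
# All times in minutes; rates in micromol/L/min on the reference basis.
scenario: ammonia-ucd
protocol:
  onset: 1440              # disease starts after 1 day
  ramp_duration: 5760      # linear OTC activity loss over 4 days
  upregulation_delay: 360  # glutamine/alanine demands rise 6 h later
  upregulation_factor: 4
  total_duration: 30240    # 21 days
calibration:
  target_venous_uM: 29
  production: 0.694
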