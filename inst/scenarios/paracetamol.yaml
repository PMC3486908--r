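# Paracetamol dosing and liver-function robustness scan: defaults.
scenario: paracetamol
dose_g: 1
duration: 1440
max_inhibition_at_15g_peak:   # fraction of activity LOST at the peak
  THFDH: 0.25
  GDH: 0.25
  ATPS: 0.60
  GSH: 0.80
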