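# Example somnopose run configuration; unspecified fields keep defaults.
maf_window: 10
pressure_threshold: 0.5
thermal_offset: 2.0
fcm:
  m: 2
  epsilon: 1.0e-5
knn:
  k: 5
  weight_exponent: 2
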