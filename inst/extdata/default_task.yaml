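timing:
  stim_len: 100
  delay_len: 50
  response_len: 50
  dt: 0.1
stimulus:
  class_means:
  - - 0.5
    - 1.0
  - - 1.0
    - 0.5
  class_stds:
  - - 0.3
    - 0.3
  - - 0.3
    - 0.3
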