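# Demonstration configuration for the synthetic dynamic-FFR pipeline.
seed: 1
vessel:
  severity: 0.6
  radius: 2
  length: 40
cardiac:
  EDV: 120
  ESV: 50
  HR: 60
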