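{
  "name": "sisa-mrsa-default",
  "comment": "SISa epidemic defaults. The spontaneous-infection rate a and the normalizer N0 are pinned by the inactive-state escape-time law tau(0) = 1/(N a) (200/286/500 days at Omega = 0.25/0.175/0.1); the recovery rate g is set so that the ground-state reallocation occurs at Omega_c = 0.175; the transmission rate beta is calibrated so the macroscopic endemic fixed point is exactly 0.4719.",
  "time_unit": "day",
  "N0": 200,
  "omega": 1,
  "a": 1e-4,
  "beta": 0.10393503256425222,
  "g": 0.055
}
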