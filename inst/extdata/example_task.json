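{
  "label": "two_arm_demo",
  "arms": [
    {"family": "gaussian", "mu": 0.6, "sigma": 0.5},
    {"family": "gaussian", "mu": 0.4, "sigma": 0.5}
  ],
  "tau": 50
}
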