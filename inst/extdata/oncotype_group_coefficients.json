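{
  "GRB7": 0.47,
  "ER": -0.34,
  "proliferation": 1.04,
  "invasion": 0.10,
  "CD68": 0.05,
  "GSTM1": -0.08,
  "BAG1": -0.07
}
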