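{
  "eps": -0.5,
  "U": 0.62,
  "r": 1.4,
  "S": 0.40,
  "H": -0.70,
  "Vee": 0.45,
  "VeH": 0.50,
  "VHH": 0.7142857142857143
}
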