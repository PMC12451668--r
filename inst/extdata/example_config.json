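{
  "units": "atomic",
  "task": 1,
  "rgrid": [1.0, 1.4, 2.0],
  "reference_mode": "internal_oracle",
  "seed": 12345,
  "n_starts": 20,
  "basis": {"n": 10, "alpha0": 0.02, "beta": 2.5},
  "trimer_kind": "linear_trimer"
}
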