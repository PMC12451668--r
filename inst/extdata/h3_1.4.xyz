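3
symmetric linear hydrogen trimer units=bohr
H 0.0 0.0 0.0
H 0.0 0.0 1.4
H 0.0 0.0 2.8
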