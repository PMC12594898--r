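F1 A1 0 0 1 1
F1 A2 0 0 2 1
F1 A3 A1 A2 2 1
F1 A4 0 0 1 1
F1 A5 A4 A3 2 2
F1 A6 A4 A3 2 1
F2 B1 0 0 2 1
F2 B2 0 0 2 2
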