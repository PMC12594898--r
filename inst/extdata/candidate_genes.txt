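BRCA1
BRCA2
PALB2
CHEK2
ATM
TP53
PTEN
CDH1
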