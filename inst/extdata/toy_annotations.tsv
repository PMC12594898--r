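variant_id	gene	consequence	clinvar_significance	af
rs1001	BRCA2	stop_gained	Pathogenic	0.0021
rs1002	GREB1	frameshift	Pathogenic	0.0009
rs1003	BRCA1	missense	Pathogenic	0.0104
rs1004	PALB2	splice_donor	Uncertain_significance	0.0007
rs1005	CHEK2	frameshift	Likely_pathogenic	0.0152
rs1006	ATM	stop_gained	Benign	0.0260
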