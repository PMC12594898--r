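# Toy 6-variant weight file in the PGS-Catalog tab-separated dialect.
# Weights are per-allele natural-log odds ratios.
rsID	chr_name	chr_position	effect_allele	other_allele	effect_weight
rs1001	1	1205034	A	G	0.0512
rs1002	2	8804921	T	C	-0.0388
rs1003	5	44552012	G	A	0.0925
rs1004	9	120800312	C	A	0.0177
rs1005	11	69331421	G	T	-0.0601
rs1006	16	52599192	A	T	0.0433
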