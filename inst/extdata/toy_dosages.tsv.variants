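variant_id	counted_allele	alternate_allele
rs1001	A	G
rs1002	C	T
rs1003	G	A
rs1004	C	A
rs1005	G	T
rs1006	A	T
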