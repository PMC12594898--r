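##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	1205034	rs1001	G	A	.	PASS	.	GT	0/1	1/1	0/0
2	8804921	rs1002	T	C	.	PASS	.	GT	0/0	0/1	./.
5	44552012	rs1003	A	G	.	PASS	.	GT	1/1	0/1	0/1
9	120800312	rs1004	A	C	.	PASS	.	GT	0/1	0/0	1/1
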