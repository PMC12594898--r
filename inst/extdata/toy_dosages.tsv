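sample_id	rs1001	rs1002	rs1003	rs1004	rs1005	rs1006
A1	0	1	2	0	1	0
A2	1	0	1	1	0	1
A3	1	1	1	0	NA	2
A4	2	0	0	1	1	1
A5	1	2	1	0	0	0
A6	0	1	2	1	1	1
B1	1	1	0	0	2	0
B2	2	0	1	1	0	2
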