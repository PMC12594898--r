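sample_id	family_id	sex	age	affection	age_at_onset	bc_status	personal_history	family_history	genotyped	phenotype_complete
A1	F1	male	74	unaffected	NA	ineligible	FALSE	TRUE	TRUE	TRUE
A2	F1	female	71	unaffected	NA	control_eligible	FALSE	TRUE	TRUE	TRUE
A3	F1	female	49	unaffected	NA	control_eligible	FALSE	TRUE	TRUE	TRUE
A4	F1	male	52	unaffected	NA	ineligible	FALSE	TRUE	TRUE	TRUE
A5	F1	female	27	affected	26	case	TRUE	FALSE	TRUE	TRUE
A6	F1	female	24	unaffected	NA	control_eligible	FALSE	TRUE	TRUE	TRUE
B1	F2	female	63	unaffected	NA	control_eligible	FALSE	FALSE	TRUE	TRUE
B2	F2	female	58	affected	55	case	TRUE	FALSE	TRUE	TRUE
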