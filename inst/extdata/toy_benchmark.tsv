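species	allele	peptide_length	sequence	inequality	meas	measurement_kind	reference
human	HLA-A*31:01	9	KVFGPIHEL	=	25.0	ic50	IEDB-1000001
human	HLA-A*31:01	9	AVFDRKSDA	=	9000.0	ic50	IEDB-1000001
human	HLA-A*31:01	9	RLRPGGKKK	=	60.0	ic50	IEDB-1000001
human	HLA-A*03:01	9	RAAPPPPPR	=	1	binary	IEDB-1000002
human	HLA-A*03:01	9	TLYLVFEAL	=	0	binary	IEDB-1000002
human	HLA-B*07:02	9	APRTLVLLL	=	30.0	ic50	IEDB-1000003
human	HLA-B*07:02	9	KPIVQYDNF	=	800.0	ic50	IEDB-1000003
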