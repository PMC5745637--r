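species	allele	peptide_length	sequence	inequality	meas
human	HLA-A*31:01	9	KVFGPIHEL	=	25.0
human	HLA-A*03:01	9	RAAPPPPPR	=	100.0
human	HLA-A*68:01	9	LPQWLSANR	<	450.0
human	HLA-B*07:02	9	APRTLVLLL	>	20000.0
human	HLA-A*02:01	9	GILGFVFTL	=	500.0
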