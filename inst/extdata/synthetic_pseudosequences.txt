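# SYNTHETIC pseudo-sequence fixture for tests and examples.
# Allele names are real HLA class I alleles, but the 34-residue contact
# strings below are randomly generated stand-ins, NOT the NetMHCpan
# pseudo-sequences. Supply your own pseudo-sequence file for real use.
HLA-A*01:01 YFAMYGEKVAHTHVDTLYVRYHYYTWAVLAYTWY
HLA-A*02:01 YFAMYQENMAHTDANTLYIIYRDYTWVARVYRGY
HLA-A*03:01 YFAMYQENVAQTDVDTLYIMYRDYTWAELAYTWY
HLA-A*31:01 YTAMYQENVAQTDVDTLYIMYRDYTWAELAYLWY
HLA-A*68:01 YDAMYQENVAHTDENTLYIMYRDYTWAELAYTWY
HLA-B*07:02 YYAEYREKYAQTDESNLYLRYDYYTWAELAYEWY
HLA-B*27:05 YHTEYREKYAQTDESNLYLRYHDYTWAELAYEWY
HLA-B*57:01 YYAMYGEKVAHTDESNLYIRYDSYTWAELAYLWY
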