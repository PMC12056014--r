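gene	branch	lnl_alt	lnl_null	flag
STAU1	human	-4133.6	-4152.73	garbled
PSEN2	human	-4314.65	-4345.96	garbled
ANKK1	human	-6287.36	-6302.23	ok
ETFDH	human	-4791.55	-4847.84	ok
ZHX3	human	-7572.95	-7586.06	ok
PCDH9	human	-6267.04	-6275.47	ok
LYRM4	human	-381.331	-387.241	ok
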