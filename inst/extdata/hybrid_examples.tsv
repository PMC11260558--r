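sample_id	location	temporal_event	phenotype	date	sex	maturity	q	Q
EGM18_2385	Boysen Reservoir	NA	sauger	2015-09-10	F	mature	0.143	0.286
EGM18_2522	Boysen Reservoir	NA	walleye	2018-09-11	F	mature	0.884	0.231
EGM18_2529	Boysen Reservoir	NA	walleye	2018-09-11	F	mature	0.550	0.899
EGM18_2550	Boysen Reservoir	NA	walleye	2018-09-12	F	immature	0.801	0.398
EGM18_2562	Boysen Reservoir	NA	walleye	2018-09-12	M	mature	0.297	0.593
EGM18_0187	Middle Bighorn	spawn	walleye	2018-05-18	M	immature	0.885	0.230
EGM18_2663	Bighorn Lake	NA	sauger	2018-11-06	NA	NA	0.111	0.222
EGM18_2684	Upper Bighorn	nonspawning	sauger	2018-11-08	NA	NA	0.102	0.203
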