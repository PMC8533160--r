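enzyme	substrate	kcat	km_uM	printed_eff
PSPmod	BAPNA	91.7	188.8	0.049
PSPmod	Z-RR-pNA	157.3	11.18	1.41
PSPmod	Z-KR-pNA	592.8	124.4	0.477
PSPmodE75	BAPNA	603.1	165.5	0.364
PSPmodE75	Z-RR-pNA	960	34.65	2.77
PSPmodE75	Z-KR-pNA	805.7	24.0	3.36
PSPmodE125A	BAPNA	728.7	265.6	0.274
PSPmodE125A	Z-RR-pNA	424.0	5.92	8.15
PSPmodE125A	Z-KR-pNA	493.3	11.6	4.25
PSP	BAPNA	791.2	78.1	1.01
PSP	Z-RR-pNA	2181.2	4.35	50.1
PSP	Z-KR-pNA	3045.6	20.8	14.6
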