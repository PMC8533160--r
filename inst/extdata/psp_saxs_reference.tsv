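protein	rg	dmax	vc
PSP	27.4	80	433
PSP-Sp	27.2	76	434
PSPmodE125A	26.5	80	397
PSPmod	25.9	79	422
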