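name	ec_number	p1_residues	p1prime_residues
ficin	3.4.22.3	FY	
ficin	3.4.22.3	G	
papain	3.4.22.2	KR	
papain	3.4.22.2	FLV	AGSTVLIF
bromelain	3.4.22.32	KR	
bromelain	3.4.22.32	AY	G
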