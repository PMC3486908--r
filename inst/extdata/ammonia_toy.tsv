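reaction_id	equation	lb	ub	notes
EX_nh3	 -> nh3[c]	0	0.163	ammonia uptake
GDH	akg[c] + nh3[c] -> glu[c]	0	Inf	
GS	glu[c] + nh3[c] -> gln[c]	0	Inf	
ALT	glu[c] + pyr[c] -> akg[c] + ala[c]	0	Inf	
urea_cycle	co2[c] + 2 nh3[c] -> urea[c]	0	Inf	OTC
EX_urea	urea[c] -> 	0	Inf	
EX_gln	gln[c] -> 	0.008	0.008	
EX_ala	ala[c] -> 	0.002	0.002	
S_akg	 -> akg[c]	0	Inf	
S_pyr	 -> pyr[c]	0	Inf	
S_co2	 -> co2[c]	0	Inf	
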