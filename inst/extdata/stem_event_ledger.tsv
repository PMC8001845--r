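node	class	dups	losses	copies
Acroporidae	GFP/CFP	0	0	3
Acroporidae	RFP	0	0	1
Acroporidae	ChrP	0	0	1
Montipora_Acropora	GFP/CFP	0	0	3
Montipora_Acropora	RFP	0	0	1
Montipora_Acropora	ChrP	0	0	1
Acropora_anc	GFP/CFP	6	0	9
Acropora_anc	RFP	2	0	3
Acropora_anc	ChrP	3	0	4
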