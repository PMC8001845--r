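species	clade
Stylophora_pistillata	outgroup
Astreopora_myriophthalma	Astreopora
Montipora_cactus	Montipora
Montipora_efflorescens	Montipora
Acropora_tenuis	I
Acropora_yongei	I
Acropora_intermedia	II
Acropora_gemmifera	II
Acropora_awi	II
Acropora_florida	II
Acropora_digitifera	III
Acropora_nasuta	III
Acropora_microphthalma	III
Acropora_acuminata	III
Acropora_echinata	IV
Acropora_muricata	IV
Acropora_selago	IV
Acropora_cytherea	IV
Acropora_hyacinthus	IV
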