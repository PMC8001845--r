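((Astreopora_myriophthalma:1.0,((Montipora_cactus:0.4,Montipora_efflorescens:0.4)Montipora:0.4,((Acropora_tenuis:0.25,Acropora_yongei:0.25)CladeI:0.35,((Acropora_intermedia:0.4,(Acropora_gemmifera:0.3,(Acropora_awi:0.2,Acropora_florida:0.2)CladeIIa:0.1)CladeIIb:0.1)CladeII:0.1,((Acropora_acuminata:0.35,(Acropora_microphthalma:0.25,(Acropora_nasuta:0.15,Acropora_digitifera:0.15)CladeIIIa:0.1)CladeIIIb:0.1)CladeIII:0.1,(Acropora_echinata:0.4,(Acropora_muricata:0.3,(Acropora_selago:0.2,(Acropora_cytherea:0.1,Acropora_hyacinthus:0.1)CladeIVa:0.1)CladeIVb:0.1)CladeIVc:0.1)CladeIV:0.05)NodeIII_IV:0.05)NodeII_IV:0.1)Acropora_anc:0.2)Montipora_Acropora:0.2)Acroporidae:0.5,Stylophora_pistillata:1.5)Scleractinia;
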