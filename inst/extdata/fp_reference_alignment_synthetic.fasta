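>REF_GFPCFP_synthetic
YYNLFCRWDKFSQSFFEWVGTVKQCCKLPEELPNQSILRRWPMDLYYWMKDQPPQETESKTWQYGQDQCRTYFAVITIGRTYFWYFEFFTAVKYYDQGRDTSWTQAASLQMVWYIWKLNWECQAAFHCPFNRAMTWLNQGGQFNIMRNATRIIFVMGECACRMFSYRKRQRFDHGLPHRDKHRIFVHQLYHMHSHQIACCSTFLYGMVMVLWMECGVLVTGQGCCQNEAF
>REF_GFPCFP_v1_synthetic
YYNPFCRWDKFSQSFFEWVGTVKMCCKLPEELANQEILRRWPMDLYYHMKDQPPQETESKTWQYGQDQCRTYFAVITIVNTYFWYFEFFTAVKYYDQGRDTSWTQAASLQMVWYIWKLNWECQAADHCPFNRAMTWLNQGGQFNIMRNATRIIFVMGECACRMFSYRKRQRFDHGLPNRDKHRIFVHQLYHMHSHQIACCSTFLYGMVMVLWMECGVMVTGQGCIQNEAF
>REF_GFPCFP_v2_synthetic
YYNLFCRWTKFSQSFFEWVGTVKQCCKLPEELLNQSILRRWMMDLYYWMKDQPPQETESKTWQYGQDQCRTYFARITIGRTYFWYFEFFTAVKYYDQGRDTSWTQAASLQMVWYIWKLNWECQAAFHCPFLRAMTWLNFGGGFNIMRNATRIIFVMGECACRMFPYRKRQRFDHGLPHRNKHRIFVHQLYHMHSIQIACCSTFLYGMVMVLWMECGVLVTGQGCCQNHAF
>REF_RFP_synthetic
AYNLHCRWDQFSQSFIIWCGTGKQCTKLPIELPKQSILRRWPMDLYYWMKDQPRQENESKTWDYGQDQCRFYFAKITIECAKGWCFEFETADYYYDTGRDTSWFQAASLQMVWAFWKLNWECCAECHHKFNRAMTFLAQDGFFWIMENITRGIFVMGECARRMLSYRIIQRMEWGVPHRDKHRIFVHQLYHMHSHQIDCCSTRLYGMQCVLWMHCIVLVTFQGCCPNETF
>REF_RFP_v1_synthetic
AYNLQCRWDQFSQSFIIWCGTGKQCTKIPIELPKQSILRRWPMDLYYWMKDQPRQENESKTWDYGQDQCRFYFAKISIECAKGHCFEFETADYYYDTGRDTSWFMAASLQMVWAQWKLNWECCAECHHKFNRAMTFLAQDGNFWIMENITRGIFVMGECAYGMLSYRIIQRMEWGVPHRDKHRIFVHQLYHMHSHQIDCCSTILYGMQCVLWMHCISLVTFQGCCPNETF
>REF_RFP_v2_synthetic
AYNLHCRWDQFSQSFIIWCGTIKQCTKLPIELPKQSILRRWPMDLYYWMKDQPRQENESKTWDYGQDQCRFYFAKITIECAKSWCFEFETADYYYDTGRDTSWFQAASLQMVWAFWKLNWECCAECHHKFNRAMTFLAQDGFFWFMENITRHIFVMGEWARRMVSYRIIQRMEWGVPHRDKHRIFVHQLAHMHSHQIDCCSGRLYGMQCVRWMHCIVKVTFQGCCPNETD
>REF_ChrP_synthetic
YYNLFFRWDTFSQSFFEPTGTVKQCCKLPQELPNQSILRRWMMDYAYWMKDLPPQETEWKAWQYGQYQCRFYFAVNTIRRIYFPYEEFFTAVFYYDQKSDYSWQQAASLQCVNYRQKLNWHCQAAQHCPFNSAMTWWNQGVLFNKMRNAMRIIFVYGECACRMFAYRKRQRFHHGLPHQDKHNIVVHQICHMHSHWISQQSTFDYGMVMWLTSNDGVPVTGQGCGQNWRF
>REF_ChrP_v1_synthetic
YYNLFFRWDTFSQSFFEPEGTVKQCCKLPQWLPNQSIQRRWMMDYAYWMKDLPPQETEWKAWQYGQYQCRFVFAVNTIRRIYFPYEEFFDAVFGYDQKSDYSWQQAASLQCVNYRQKLNWHCQAAQHCPFNSAMTWWNQGVLFNKMRKAMRIIIVYGECACRMFAYRKRQRFHHGLPHQDCHNIVVHQICHMHSHWISQQSTFDAGMVMWLTSNDGVPVTGGGCGQNWRF
>REF_ChrP_v2_synthetic
YYNGFFRWDTFSQSFPEPTGTVKQCCKLPQALPNQSILRRWMMYYAYWMHDLPPQETEWKTWQYGQYQCWFYFAVNTIRRIYFPYEEFFTAVFYYDQKSDYSWQQAASLQCVNYRQKLNWHCQAAQHCPFNSAMTWWNQKVLFNKMRNAMRIIFVYGECACHMFAYRKRQRFHHGLPHIDKHNIVVHQICHMHSHWISQQSTFDYGMVMWLDSNDGVPVTGQGCGQNWRF
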