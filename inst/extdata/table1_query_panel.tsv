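accession	description	species	color
AAU06846.1	green fluorescent protein	Acropora millepora	Green
FAA00739.1	TPA: fluorescent protein 2	Acropora digitifera	unreported
ABB17973.1	green fluorescent GFP-like protein	Acropora millepora	Green
ACH89428.1	green fluorescent protein FP512	Acropora millepora	Green
FAA00741.1	TPA: fluorescent protein 4	Acropora digitifera	unreported
FAA00743.1	TPA: fluorescent protein 6, partial	Acropora digitifera	unreported
FAA00742.1	TPA: fluorescent protein 5, partial	Acropora digitifera	unreported
AAU06851.1	cyan fluorescent protein 2	Acropora robusta	Cyan
FAA00738.1	TPA: fluorescent protein 1	Acropora digitifera	unreported
ACH53606.1	green fluorescent-like protein, partial	Acropora millepora	Green
ACH89426.1	cyan fluorescent protein FP484	Acropora millepora	Cyan
AAU06849.1	cyan fluorescent protein	Acropora millepora	Cyan
ACH89427.1	green fluorescent protein FP497	Acropora millepora	Green
FAA00740.1	TPA: fluorescent protein 3	Acropora digitifera	unreported
AAS18271.1	green fluorescent protein 2	Astrangia lajollaensis	Green
AAT77753.1	colorless GFP-like protein	Acropora millepora	Red
ACH53607.1	red fluorescent-like protein, partial	Acropora millepora	Red
ACH89429.1	red fluorescent protein FP597	Acropora millepora	Red
AAU06852.1	red fluorescent protein	Acropora millepora	Red
FAA00746.1	TPA: fluorescent protein 10	Acropora digitifera	unreported
ACD13194.1	green fluorescent GFP-like protein	Platygyra lamellina	Cyan
ABB17955.1	cyan fluorescent GFP-like protein	Mycedium elephantotus	Green
AAM10625.3	green fluorescent protein	Dendronephthya sp. SSAL-2002	Green
ABB17949.1	GFP-like chromoprotein	Goniopora djiboutiensis	Non-fluorescent
FAA00744.1	TPA: fluorescent protein 7, partial	Acropora digitifera	unreported
FAA00745.1	TPA: fluorescent protein 9, partial	Acropora digitifera	unreported
BAM10197.1	fluorescent protein 8	Acropora digitifera	unreported
AAU06854.1	chromoprotein	Acropora millepora	Non-fluorescent
AAG16224.1	red fluorescent protein	Discosoma sp. SSAL-2000	Red
AAF03370.1	fluorescent protein FP483	Discosoma striata	unreported
XP_001634522.1	predicted protein	Nematostella vectensis	unreported
XP_001633713.1	predicted protein	Nematostella vectensis	unreported
AAN05449.1	red fluorescent protein FP611	Entacmaea quadricolor	Red
AAL27541.1	GFP-like chromoprotein	Condylactis passiflora	Green
AAK71342.1	cgigFP-g	Condylactis gigantea	Non-fluorescent
AAQ01187.1	green fluorescent protein 2	Pontella meadi	Green
AAQ01186.1	green fluorescent protein 1	Pontella meadi	Green
BAE78442.1	green fluorescent protein	Chiridius poppei	Green
AAR85351.1	green fluorescent protein 2	Anthomedusae sp. SL-2003	Green
AAR85350.1	green fluorescent protein 1	Anthomedusae sp. SL-2003	Green
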