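case_id	sex	gene	moi	variant	zygosity	origin	category	partial
1004	F	EP300	AD	c.5723dupC (p.Thr1909Asnfs*164)	het	N/A	1	FALSE
1006	M	MC4R	AD	c.751A>C (p.Ile251Leu)	het	MA	2	TRUE
1008	M	SMARCB1	AD	c.364del (p.Glu122Asnfs*21)	het	N/A	1	FALSE
1009	M	LARP7	AR	c.756_757del (p.Arg253Ile*6)	hom	MA/P	2	FALSE
1012	M	KAT6B	AD	c.3021+1G>C (p?)	het	DN	1	FALSE
1015	M	GDF5	AD	c.847G>A (p.Val283Met)	het	DN	2	FALSE
1016	F	PANK2	AR	c.824_825del (p.Cys276Trpfs*15)	hom	MA/P	2	FALSE
1023	F	NGLY1	AR	c.1201A>T (p.Arg401*)	hom	MA/P	2	FALSE
1029	F	PIK3R2	AD	c.1117G>A (p.Gly373Arg)	het	DN	2	FALSE
1032	F	SPTAN1	AD	c.6947A>C (p.Gln2316Pro)	het	DN	1	FALSE
1040	M	EXT2	AD	c.1760C>T (p.Thr587Met)	het	N/A	1	TRUE
1045	M	TSEN54	AR	c.919G>T (p.Ala307Ser)	hom	MA/P	1	FALSE
1049	F	NSD1	AD	c.3922-1G>C (p?)	het	N/A	1	FALSE
1050	M	CBL	AD	c.1096-11_1109del (p?)	het	DN	1	FALSE
1055	F	PACS1	AD	c.607C>T (p.Arg203Trp)	het	DN	2	FALSE
1057	F	SETD5	AD	c.1576_1580del (p.Glu526Lysfs*15)	het	DN	2	FALSE
1059	M	PIK3R1	AD	c.1993G>A (p.Gly665Ser)	het	P	1	FALSE
1062	M	GJB2	AR	c.35delG (p.Gly12fs*2)	hom	MA/P	1	TRUE
1066	M	CCM2	AD	c.1054delG (p.Gly352Val*2)	het	P	1	TRUE
1070	F	VWF	AD	c.6187C>T (p.Pro2063Ser)	hom	MA/P	1	TRUE
1078	M	TYR	AR	c.1118C>A (p.Thr373Lys)/c.1205G>A (p.Arg402Gln)	het/het	MA/P	1	FALSE
1078	M	MC4R	AD	c.307G>A (p.Val103Ile)	het	N/A	2	FALSE
1080	M	COL4A1	AD	c.2317G>A (p.Gly773Arg)	het	DN	1	FALSE
1089	M	PLVAP	AR	c.1072C>T (p.Arg358*)	hom	MA/P	3	FALSE
1093	F	NGLY1	AR	c.517A>G (p.Arg173Gly)	hom	MA/P	2	FALSE
1093	F	COG5	AR	c.1205C>T (p.Ser402Leu)	hom	MA/P	1	FALSE
1102	M	ATP1A3	AD	c.2452G>A (p.Glu818Lys)	het	DN	1	TRUE
1103	F	VPS53	AR	c.1429C>T (p.Arg477*)/c.1716T>G (p.Ser572Arg)	het/het	MA/P	2	FALSE
1107	F	SMARCA2	AD	c.2639C>T (p.Thr880Ile)	het	DN	1	FALSE
1108	F	ALDH18A1	AR	c.1321C>T (p.Arg441*)/c.191G>A (p.Arg64His)	het/het	MA/P	2	FALSE
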