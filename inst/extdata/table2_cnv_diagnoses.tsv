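case_id	sex	chrom	cma_start	cma_end	size_kb	state	wgs_start	wgs_end	origin	category	partial	locus
1090	F	chrX	60701	91873056	91813	loss	176000	91866000	DN	1	TRUE	chrX_complex_rearrangement
1090	F	chrX	91877172	155174078	63297	gain	92796000	155260560	DN	1	TRUE	chrX_complex_rearrangement
1005	M	chr4	33574	7608090	7575	loss	68000	7616000	DN	1	FALSE	chr4:33574-7608090
1034	F	chr22	18713432	21440515	2727	loss	18888000	21466000	DN	1	FALSE	chr22:18713432-21440515
1022	F	chr10	30822400	32872626	2050	loss	30814000	32892000	DN	2	FALSE	chr10:30822400-32872626
1026	M	chr22	35931002	37272620	1342	loss	35890000	37302000	N/A	3	FALSE	chr22:35931002-37272620
1066	M	chr8	97145564	98301541	1156	loss	97134000	98308000	DN	2	TRUE	chr8:97145564-98301541
1027	F	chr16	15507164	16400833	894	loss	15480000	16296000	DN	2	FALSE	chr16:15507164-16400833
1102	M	chr2	51021507	51358841	337	loss	51020000	51374000	DN	2	TRUE	chr2:51021507-51358841
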