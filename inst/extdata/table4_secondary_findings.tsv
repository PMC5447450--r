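case_id	sex	gene	inheritance	variant	zygosity	condition	also_primary
1003	F	FBN1	AD	c.3509G>A p.Arg1170His	het	Marfan syndrome	FALSE
1027	F	COL3A1	AD	c.812G>A p.Arg271Gln	het	Ehlers-Danlos syndrome type III/IV	TRUE
1040	M	SCN5A	AD/AR	c.5239G>A p.Val1747Met	het	Brugada syndrome 1 and related cardiac conduction disorders	TRUE
1063	F	KCNH2	AD	c.3278C>T p.Pro1093Leu	het	Long QT syndrome; Short QT syndrome	FALSE
1067	M	SCN5A	AD/AR	c.5336C>T p.Thr1779Met	het	Brugada syndrome 1 and related cardiac conduction disorders	FALSE
1078	M	RYR2	AD	c.3320C>T p.Thr1107Met	het	Arrhythmogenic right ventricular dysplasia 2; catecholaminergic polymorphic ventricular tachycardia	TRUE
1091	M	DSG2	AD	c.2434G>A p.Gly812Ser	het	Arrhythmogenic right ventricular dysplasia 10; dilated cardiomyopathy 1BB	FALSE
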