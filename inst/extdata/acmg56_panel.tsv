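gene	inheritance	condition
APC	AD	Familial adenomatous polyposis
MYH11	AD	Familial thoracic aortic aneurysm and dissection
ACTA2	AD	Familial thoracic aortic aneurysm and dissection
TMEM43	AD	Arrhythmogenic right ventricular cardiomyopathy
DSP	AD	Arrhythmogenic right ventricular cardiomyopathy
PKP2	AD	Arrhythmogenic right ventricular cardiomyopathy
DSG2	AD	Arrhythmogenic right ventricular cardiomyopathy
DSC2	AD	Arrhythmogenic right ventricular cardiomyopathy
BRCA1	AD	Hereditary breast and ovarian cancer
BRCA2	AD	Hereditary breast and ovarian cancer
SCN5A	AD/AR	Brugada syndrome; long QT syndrome 3
RYR2	AD	Catecholaminergic polymorphic ventricular tachycardia
LMNA	AD	Dilated cardiomyopathy
MYBPC3	AD	Hypertrophic cardiomyopathy
COL3A1	AD	Ehlers-Danlos syndrome vascular type
GLA	XL	Fabry disease
LDLR	AD	Familial hypercholesterolaemia
MYH7	AD	Hypertrophic cardiomyopathy
TPM1	AD	Hypertrophic cardiomyopathy
PRKAG2	AD	Hypertrophic cardiomyopathy
TNNI3	AD	Hypertrophic cardiomyopathy
MYL3	AD	Hypertrophic cardiomyopathy
MYL2	AD	Hypertrophic cardiomyopathy
ACTC1	AD	Hypertrophic cardiomyopathy
RET	AD	Multiple endocrine neoplasia type 2
PCSK9	AD	Familial hypercholesterolaemia
BMPR1A	AD	Juvenile polyposis
SMAD4	AD	Juvenile polyposis
TNNT2	AD	Hypertrophic cardiomyopathy
KCNQ1	AD	Long QT syndrome 1
KCNH2	AD	Long QT syndrome 2
MLH1	AD	Lynch syndrome
MSH2	AD	Lynch syndrome
MSH6	AD	Lynch syndrome
PMS2	AD	Lynch syndrome
RYR1	AD	Malignant hyperthermia susceptibility
CACNA1S	AD	Malignant hyperthermia susceptibility
FBN1	AD	Marfan syndrome
TGFBR1	AD	Loeys-Dietz syndrome
TGFBR2	AD	Loeys-Dietz syndrome
SMAD3	AD	Loeys-Dietz syndrome
MEN1	AD	Multiple endocrine neoplasia type 1
MUTYH	AR	MYH-associated polyposis
NF2	AD	Neurofibromatosis type 2
SDHD	AD	Hereditary paraganglioma-phaeochromocytoma
SDHAF2	AD	Hereditary paraganglioma-phaeochromocytoma
SDHC	AD	Hereditary paraganglioma-phaeochromocytoma
SDHB	AD	Hereditary paraganglioma-phaeochromocytoma
STK11	AD	Peutz-Jeghers syndrome
PTEN	AD	PTEN hamartoma tumour syndrome
RB1	AD	Retinoblastoma
TP53	AD	Li-Fraumeni syndrome
TSC1	AD	Tuberous sclerosis complex
TSC2	AD	Tuberous sclerosis complex
VHL	AD	Von Hippel-Lindau syndrome
WT1	AD	WT1-related Wilms tumour
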