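gene_symbol	gene_name	accession	mPea3	hPea3
ACTN2	Actinin, alpha 2	2058	0	9,45
ADAM10	ADAM metallopeptidase domain 10	14166	0	9,45
ANGPT-1	Angiopoietin	113693	0	0,43
APC	Adenomatous polyposis coli	33308	0,63	9,45
BMP2	Bone morphogenic protein 2	113729	8,32	9,67
CDH1	Cadherin 1, type 1, E-cadherin (epithelial)	15369	3,94	N/A
CDK5R1	Cyclin-dependent kinase 5, regulatory subunit 1	115721	N/A	9,45
CIB1	Calcium and integrin binding 1 (calmyrin)	13845	4,38	0,21
CSF1	Colony stimulating factor 1 (macrophage)	112668	1,07	9,45
CST3	Tachykinin receptor 1	25458	7,25	N/A
CX3CR1	Chemokine (C-X3-C motif) receptor 1	30958	0,63	0
DCLK1	Doublecortin-like kinase	11447	3,94	7,14
DIAPH1	Diaphanous homolog I (Drosophila)	34180	1,7	0,21
DPYSL2	dihydropyrimidinase-like 2	39825	0,63	7,14
DRD5	Dopamine receptor D5	31284	1,07	7,14
DYX1C1	Dyslexia susceptibility 1 candidate 1	124118	8,32	9,45
EGR1	Early growth response 1	33479	3,31	7,14
FES	Feline sarcoma oncogene	13679	3,31	9,45
GMIP	GEM interacting protein	120115	3,94	N/A
GNB1	Guanine nucleotide binding protein	4136	0	9,24
GNB2L1	G protein, beta polypeptide 2-like 1	33870	N/A	6,93
HSPA4	Heat shock protein 70 kDa protein 4	33414	3,94	0,21
HSPB1	Heat shock 27 kDa protein 1	37879	1,7	N/A
IGFBP3	Insulin-like growth factor binding protein 3	39292	3,31	9,45
ILK	Integrin-linked kinase	6243	0,63	0,43
INS	Insulin	8437	3,94	9,67
IRS2	Insulin receptor substrate 2	11182	N/A	9,45
ITGA5	Integrin, alpha 5 (fibronectin receptor, alpha polypeptide)	10119	0,63	N/A
KAL1	Kalmann syndrome 1 sequence	44617	0,63	9,45
LIMK1	Lim kinase 1	37847	3,94	0
MAP3K5	Mitogen-activated protein kinase kinase kinase 5	36258	0,63	0
MAPK8IP3	Mitogen-activated protein kinase 8 interacting protein 3	14609	3,94	7,14
MMP9	matrix metallopeptidase 9	26338	0	6,93
NDN	Necdin homolog (mouse)	1442	0,63	0
NRAS	Neuroblastoma RAS viral (v-ras) oncogene homolog	3139	3,31	0,21
NRXN1	Neurexin 1	116392	3,31	N/A
PDPK1	3-phosphoinositide dependent protein kinase-1	14469	0	9,45
PRKCA	Protein kinase C, alpha	114871	0	9,45
PTEN	Phosphatase and tensin homolog	4722	1,7	7,36
PTGS2	Prostaglandin-endoperoxide synthase 2	112626	3,94	9,45
PTK2	Protein Tyrosine Kinase 2	116986	0,63	0
PTK2B	Protein tyrosine kinase 2 beta	39829	0	0
PTPN1	Protein tyrosine phosphatase, non-receptor type 1	26382	0	0,21
RB1CC1	RB1-inducible coiled-coil 1	40992	3,31	N/A
RGMA	RGM Domain Family Member B	33277	3,31	N/A
RGMB	RGM Domain Family Member A	13823	3,94	0
RRAS	Related RAS viral (r-ras) oncogene homolog	21730	3,94	7,14
SEMA3B	Semaphorin 3B	29403	0	9,24
SEMA4A	Semaphorin 4A	1354	3,94	9,67
SGK1	Serum/glucocorticoid regulated kinase 1	36274	6,61	6,93
TBX21	T-box 21	17380	0,63	9,67
TP53	Tumor protein p53	19095	3,94	9,45
TPM3	Tropomyosin 3	20450	1,7	9,45
TSC2	Tuberous sclerosis 2	14637	0	0,43
UNC5B	UNC5-homolog b	4599	0	N/A
WASL	Wiskott-Aldirich syndrome-like	38866	6,61	6,93
WT1	Wilm's tumor 1	8172	0,63	9,45
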