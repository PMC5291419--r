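gene_symbol	gene_name	accession	mPea3	hPea3	annotation
BDNF	Brain Derived Neurotrophic factor	8188	0,63	N/A	Growth factor activity (cell-cell signaling)
CDK5R1	Cyclin Dependent Kinase 5 regulatory subunit 1	115721	N/A	9,45	Calcium ion binding, protein kinase activity (cell-cell signaling)
CNTN2	Contactin 2	1782	3,94	9,24	Carbonhydrate and glycoprotein binding (adhesion)
EphA8	Ephrin Receptor A8	318	3,94	N/A	ATP binding, nucleotide binding and receptor activity (cell-cell signaling)
EphB2	Ephrin Receptor B2	323	N/A	9,67	Ephrin receptor activity, nucleotide binding, protein tyrosine kinase activity (cell-cell signaling)
GNAI2	Guanine nucleotide binding protein (G protein) alpha inhibiting activity polypeptide 2	29399	1,70	9,67	GTPase activity, signal transducer (cell-cell signaling)
KAL1	Kallmann syndrome 1 sequence	44617	0,63	9,45	Extracellular matrix structural constituent (structural)
L1CAM	L1 Cell adhesion molecule	113184	0,63	0	Identical protein binding (adhesion)
MAPK8IP3	mitogen-activated protein kinase 8 interacting protein 3	14609	3,94	7,14	MAP kinase scaffold activity (cell-cell signaling)
MYH10	myosin, heavy chain 10, non-muscle	19064	6,61	N/A	Actin binding, microfilament motor activity (structural)
NCAM1	Neural Cell Adhesion Molecule 1	7078	0	0,43	Identical protein binding (adhesion)
NEUROG2	Neurogenin 2	32273	0,63	0,21	Sequence-specific DNA binding (Transcription Factor)
NGFR	Nerve growth factor receptor	17440	1,70	9,24	Receptor and signal transducer activity (cell-cell signaling)
NRCAM	Neuronal cell adhesion molecule	38906	8,32	9,67	Ankyrin binding (adhesion)
Nrp1	Neuropilin 1	5859	3,31	9,24	Growth factor binding (cell-cell signaling)
NTF3	Neurotrophin 3	8613	0	7,14	Receptor binding (cell-cell signaling)
PTK2	Protein Tyrosine Kinase 2	116986	0,63	0	Nucleotide binding and signal transducer activity (cell-cell signaling)
SEMA4A	Semaphorin 4A	1354	3,94	9,67	Receptor activity (adhesion)
SLIT2	Slit Homolog 2	116382	3,94	0,43	GTPase inhibition, Roundabout binding, calcium ion binding (adhesion)
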