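gene_symbol	species_origin	itraq_experiment	mapped_human_entrez_id	n_unique_peptides
MBP	Rat	iTRAQ2	4155	12
MAG	-	iTRAQ1	4099	9
NFL	-	iTRAQ1	4747	16
MBP	-	iTRAQ1	4155	23
CROCC	-	iTRAQ1	9696	2
MYPR	-	iTRAQ1	5354	10
NFM	Rat	iTRAQ1	4741	17
BCAS1	-	iTRAQ1	8537	8
BASP	Rat	iTRAQ2	10409	16
GPR37	Rat	iTRAQ1	2861	5
NFM	Rat	iTRAQ2	4741	23
MYPR	Human	iTRAQ2	5354	7
PACN1	-	iTRAQ2	29993	7
NFL	-	iTRAQ2	4747	22
NFASC	Rat	iTRAQ2	23114	15
NDRG2	-	iTRAQ1	57447	4
GBG3	-	iTRAQ2	2785	3
PRAX	-	iTRAQ2	57716	6
NDRG2	-	iTRAQ2	57447	3
AT2B3	-	iTRAQ2	492	3
NEGR1	-	iTRAQ2	257194	3
MAG	-	iTRAQ2	4099	3
ITPR1	-	iTRAQ2	3708	2
BSN	Rat	iTRAQ2	8927	84
PDK1	-	iTRAQ1	5163	4
GNAO1	-	iTRAQ2	2775	18
ITPR1	Rat	iTRAQ1	3708	2
KCC2B	Rat	iTRAQ2	816	14
NFH	Rat	iTRAQ2	4744	26
SNP25	Human	iTRAQ2	6616	11
SEPT4	-	iTRAQ1	5414	6
NFH	Rat	iTRAQ1	4744	20
SPTN2	Rat	iTRAQ2	6712	45
SYUA	-	iTRAQ2	6622	2
KCC2B	-	iTRAQ1	816	13
SYT2	-	iTRAQ2	127833	4
LGI1	-	iTRAQ2	9211	6
AT2B1	-	iTRAQ2	490	30
CCG3	-	iTRAQ2	10368	2
PP2BA	-	iTRAQ2	5530	10
CAMKV	-	iTRAQ2	79012	7
ALDOC	Rat	iTRAQ2	230	12
NEGR1	-	iTRAQ1	257194	2
BASP	Rat	iTRAQ1	10409	16
PCD10	-	iTRAQ2	57575	2
SYN2	Rat	iTRAQ2	6854	16
VISL1	Human	iTRAQ2	7447	5
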