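case_id	age	sex	race	all	dloop	mother_all	mother_shared	mother_dloop	mother_dloop_shared	father_all	father_shared	father_dloop	father_dloop_shared	fa_summary	nuclear_clinvar	mtdna_clinvar
MA02010	27 years	Male	African-American	17	5	NA	NA	NA	NA	NA	NA	NA	NA	-	TTR (amyloidosis)	MT-ND1 (SIDS)
MA00066	27 years	Female	African-American	16	5	NA	NA	NA	NA	NA	NA	NA	NA	Aneurysm	-	MT-ND1 (SIDS)
MA00056	8 months	Female	Hispanic	15	9	15	15	9	9	6	6	4	4	-	-	MT-TC, MT-TT
MA04004	24 years	Male	White	12	4	NA	NA	NA	NA	NA	NA	NA	NA	HCM	-	MT-RNR1 (HCM)
MA00025	21 years	Male	NA	12	7	NA	NA	NA	NA	NA	NA	NA	NA	-	-	MT-TQ
MA00017	9 months	Male	African-American	11	4	NA	NA	NA	NA	NA	NA	NA	NA	-	HCN4 (BrS)	MT-TA, MT-TL2
MA00011	3 months	Male	White	11	5	11	11	5	5	0	0	0	0	-	RYR2 (CPVT)	MT-ND5 x 3 (LHON)
MA00005	3 months	Male	White	10	4	10	10	4	4	0	0	0	0	-	-	MT-TE, MT-ND5 x 2 (LHON)
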