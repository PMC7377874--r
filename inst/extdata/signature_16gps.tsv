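# 16-gene-pair EMT signature (ovarian cancer); 18 genes, anchors COL5A2 and FAP
# mesenchymal-indicative pattern: rank(gene_a) < rank(gene_b)
# fisher_p: one-sided Fisher exact P for reversal enrichment in mesenchymal samples (training cohort)
# reversal_ratio: proportion of mesenchymal training samples with gene_a < gene_b
pair_id	gene_a	gene_b	fisher_p	reversal_ratio
pair_01	APMAP	COL5A2	4.22e-83	0.8023
pair_02	PUM1	COL5A2	1.23e-76	0.7733
pair_03	SERBP1	COL5A2	9.85e-76	0.7674
pair_04	HNRNPR	COL5A2	7.80e-75	0.7500
pair_05	TRIP12	COL5A2	5.92e-74	0.7558
pair_06	SHFM1	COL5A2	4.44e-73	0.7500
pair_07	SULT1A2	FAP	2.09e-79	0.7907
pair_08	EXOSC2	FAP	2.50e-79	0.7791
pair_09	ZNF20	FAP	1.79e-78	0.7849
pair_10	EWSR1	FAP	1.50e-77	0.7791
pair_11	SMCHD1	FAP	1.23e-76	0.7733
pair_12	DNAJC8	FAP	1.03e-75	0.7558
pair_13	TAF12	FAP	7.71e-75	0.7616
pair_14	ZNF3	FAP	7.71e-75	0.7616
pair_15	BCL7B	FAP	7.71e-75	0.7616
pair_16	UTP20	FAP	5.92e-74	0.7558
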