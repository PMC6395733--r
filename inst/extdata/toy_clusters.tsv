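cluster_id	gene_id	position	smcog_id	category	domain_prob	compound_class	curated_flag	organism
c01	c01_g1	0	P1	other	NA	pk	TRUE	NA
c01	c01_g2	1	P2	other	NA	pk	TRUE	NA
c01	c01_g3	2	P3	other	NA	pk	TRUE	NA
c01	c01_g4	3	B1	other	NA	pk	TRUE	NA
c01	c01_g5	4	UNASSIGNED	other	NA	pk	TRUE	NA
c02	c02_g1	0	B2	other	NA	nrp	FALSE	NA
c02	c02_g2	1	P3	other	NA	nrp	FALSE	NA
c02	c02_g3	2	P1	other	NA	nrp	FALSE	NA
c02	c02_g4	3	P2	other	NA	nrp	FALSE	NA
c02	c02_g5	4	UNASSIGNED	other	NA	nrp	FALSE	NA
c03	c03_g1	0	P2	other	NA	terpene	FALSE	NA
c03	c03_g2	1	P3	other	NA	terpene	FALSE	NA
c03	c03_g3	2	P1	other	NA	terpene	FALSE	NA
c03	c03_g4	3	UNASSIGNED	other	NA	terpene	FALSE	NA
c03	c03_g5	4	B3	other	NA	terpene	FALSE	NA
c04	c04_g1	0	P1	other	NA	pk	FALSE	NA
c04	c04_g2	1	P2	other	NA	pk	FALSE	NA
c04	c04_g3	2	P3	other	NA	pk	FALSE	NA
c04	c04_g4	3	B4	other	NA	pk	FALSE	NA
c04	c04_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c05	c05_g1	0	B3	other	NA	pk	FALSE	NA
c05	c05_g2	1	P3	other	NA	pk	FALSE	NA
c05	c05_g3	2	P1	other	NA	pk	FALSE	NA
c05	c05_g4	3	P2	other	NA	pk	FALSE	NA
c05	c05_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c06	c06_g1	0	B4	other	NA	nrp	FALSE	NA
c06	c06_g2	1	B3	other	NA	nrp	FALSE	NA
c06	c06_g3	2	B2	other	NA	nrp	FALSE	NA
c06	c06_g4	3	B1	other	NA	nrp	FALSE	NA
c06	c06_g5	4	UNASSIGNED	other	NA	nrp	FALSE	NA
c07	c07_g1	0	B2	other	NA	terpene	FALSE	NA
c07	c07_g2	1	UNASSIGNED	other	NA	terpene	FALSE	NA
c07	c07_g3	2	B2	other	NA	terpene	FALSE	NA
c07	c07_g4	3	B4	other	NA	terpene	FALSE	NA
c07	c07_g5	4	UNASSIGNED	other	NA	terpene	FALSE	NA
c08	c08_g1	0	B3	other	NA	pk	FALSE	NA
c08	c08_g2	1	UNASSIGNED	other	NA	pk	FALSE	NA
c08	c08_g3	2	UNASSIGNED	other	NA	pk	FALSE	NA
c08	c08_g4	3	UNASSIGNED	other	NA	pk	FALSE	NA
c08	c08_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c09	c09_g1	0	B2	other	NA	pk	FALSE	NA
c09	c09_g2	1	UNASSIGNED	other	NA	pk	FALSE	NA
c09	c09_g3	2	UNASSIGNED	other	NA	pk	FALSE	NA
c09	c09_g4	3	B4	other	NA	pk	FALSE	NA
c09	c09_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c10	c10_g1	0	B2	other	NA	nrp	FALSE	NA
c10	c10_g2	1	B1	other	NA	nrp	FALSE	NA
c10	c10_g3	2	UNASSIGNED	other	NA	nrp	FALSE	NA
c10	c10_g4	3	UNASSIGNED	other	NA	nrp	FALSE	NA
c10	c10_g5	4	B4	other	NA	nrp	FALSE	NA
c11	c11_g1	0	B4	other	NA	terpene	FALSE	NA
c11	c11_g2	1	B2	other	NA	terpene	FALSE	NA
c11	c11_g3	2	UNASSIGNED	other	NA	terpene	FALSE	NA
c11	c11_g4	3	B1	other	NA	terpene	FALSE	NA
c11	c11_g5	4	B4	other	NA	terpene	FALSE	NA
c12	c12_g1	0	UNASSIGNED	other	NA	pk	FALSE	NA
c12	c12_g2	1	UNASSIGNED	other	NA	pk	FALSE	NA
c12	c12_g3	2	B3	other	NA	pk	FALSE	NA
c12	c12_g4	3	B4	other	NA	pk	FALSE	NA
c12	c12_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c13	c13_g1	0	UNASSIGNED	other	NA	pk	FALSE	NA
c13	c13_g2	1	B4	other	NA	pk	FALSE	NA
c13	c13_g3	2	B1	other	NA	pk	FALSE	NA
c13	c13_g4	3	B1	other	NA	pk	FALSE	NA
c13	c13_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c14	c14_g1	0	UNASSIGNED	other	NA	nrp	FALSE	NA
c14	c14_g2	1	UNASSIGNED	other	NA	nrp	FALSE	NA
c14	c14_g3	2	B2	other	NA	nrp	FALSE	NA
c14	c14_g4	3	UNASSIGNED	other	NA	nrp	FALSE	NA
c14	c14_g5	4	B4	other	NA	nrp	FALSE	NA
c15	c15_g1	0	UNASSIGNED	other	NA	terpene	FALSE	NA
c15	c15_g2	1	B3	other	NA	terpene	FALSE	NA
c15	c15_g3	2	UNASSIGNED	other	NA	terpene	FALSE	NA
c15	c15_g4	3	B2	other	NA	terpene	FALSE	NA
c15	c15_g5	4	B2	other	NA	terpene	FALSE	NA
c16	c16_g1	0	B1	other	NA	pk	FALSE	NA
c16	c16_g2	1	B3	other	NA	pk	FALSE	NA
c16	c16_g3	2	B4	other	NA	pk	FALSE	NA
c16	c16_g4	3	UNASSIGNED	other	NA	pk	FALSE	NA
c16	c16_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c17	c17_g1	0	B2	other	NA	pk	FALSE	NA
c17	c17_g2	1	B3	other	NA	pk	FALSE	NA
c17	c17_g3	2	UNASSIGNED	other	NA	pk	FALSE	NA
c17	c17_g4	3	B1	other	NA	pk	FALSE	NA
c17	c17_g5	4	UNASSIGNED	other	NA	pk	FALSE	NA
c18	c18_g1	0	B1	other	NA	nrp	FALSE	NA
c18	c18_g2	1	B4	other	NA	nrp	FALSE	NA
c18	c18_g3	2	B1	other	NA	nrp	FALSE	NA
c18	c18_g4	3	UNASSIGNED	other	NA	nrp	FALSE	NA
c18	c18_g5	4	B4	other	NA	nrp	FALSE	NA
c19	c19_g1	0	B2	other	NA	terpene	FALSE	NA
c19	c19_g2	1	B4	other	NA	terpene	FALSE	NA
c19	c19_g3	2	B4	other	NA	terpene	FALSE	NA
c19	c19_g4	3	B1	other	NA	terpene	FALSE	NA
c19	c19_g5	4	UNASSIGNED	other	NA	terpene	FALSE	NA
c20	c20_g1	0	B3	other	NA	pk	FALSE	NA
c20	c20_g2	1	B2	other	NA	pk	FALSE	NA
c20	c20_g3	2	B4	other	NA	pk	FALSE	NA
c20	c20_g4	3	UNASSIGNED	other	NA	pk	FALSE	NA
c20	c20_g5	4	B2	other	NA	pk	FALSE	NA
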