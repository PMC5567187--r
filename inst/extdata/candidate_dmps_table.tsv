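# Worked-example differentially-methylated-probe rows matching the candidate
# SNP table: one probe per candidate gene, transcribed from the same
# published candidate table (probe id, BH-adjusted p, CpG-island relation,
# t-statistic). "open_sea" encodes the table's "." (no island feature);
# `position` is a SYNTHETIC placeholder coordinate (see the SNP table header)
# constructed so that no SNP falls inside a probe's 2-bp CpG interval.
# Where the extracted table text made the t-statistic / gene-degree boundary
# ambiguous, the tokenisation corroborated by the source's running text was
# used (IGHMBP2 t=-5.70 degree=31; PCNX t=5.34 degree=31; WDR35 t=6.0
# degree=0). pathway_overlap/validated flags for rows carrying a single
# un-positioned "Yes" are an interpretation documented in the package.
# Rows with nonempty `distractor_reason` belong to the synthetic distractor
# genes of the SNP table.
gene_symbol	probe_id	dmp_p_bh	island_relation	t_stat	chromosome	position	degree	pathway_overlap	validated	distractor_reason
DLG1	cg12594803	0.0288	open_sea	-7.04	chr3	5001000	6	TRUE	TRUE	
KIAA1147	cg24662653	2.90e-3	Island	-6.51	chr7	5002000	2	FALSE	TRUE	
GGA1	cg21268578	0.028	open_sea	-7.16	chr22	5003000	21	FALSE	FALSE	
IGHMBP2	cg26065952	0.0231	N_Shore	-5.70	chr11	5004000	31	FALSE	TRUE	
ASPM	cg11336294	0.0273	open_sea	-5.59	chr1	5005000	NA	TRUE	FALSE	
PRSS36	cg14301190	4.90e-3	Island	-6.68	chr16	5006000	1	FALSE	FALSE	
CNKSR1	cg09890400	0.0196	open_sea	-8.83	chr1	5007000	11	TRUE	FALSE	
UBTD2	ch.5.3268483F	4.90e-3	open_sea	-5.84	chr5	5008000	12	FALSE	TRUE	
FAH	cg06856840	0.0165	open_sea	-6.95	chr15	5009000	2	TRUE	FALSE	
NEDD9	cg05917225	9.20e-3	open_sea	-5.79	chr6	5010000	2	FALSE	FALSE	
BPHL	cg22799902	6.20e-3	Island	-6.43	chr6	5011000	2	FALSE	FALSE	
ACTN3	cg25117505	6.39e-6	Island	-8.39	chr11	5012000	NA	FALSE	FALSE	
WDR66	cg21016266	0.0133	Island	-4.89	chr12	5013000	3	FALSE	FALSE	
IQSEC1	cg02559896	6.70e-3	Island	-5.14	chr3	5014000	16	TRUE	FALSE	
DUOX1	cg10496082	2.00e-4	Island	-6.61	chr15	5015000	4	TRUE	FALSE	
PCDHA3	cg02357321	0.0335	N_Shore	-6.43	chr5	5016000	NA	FALSE	FALSE	
C6orf70	cg22807378	0.0121	Island	-7.15	chr6	5017000	1	FALSE	FALSE	
CLRN2	cg16760587	1.10e-3	S_Shelf	-6.06	chr4	5018000	NA	FALSE	FALSE	
COL15A1	cg18115656	0.0366	Island	5.37	chr9	5019000	0	TRUE	FALSE	
TNRC18	cg10546562	0.0101	N_Shore	5.91	chr7	5020000	28	TRUE	FALSE	
SLC26A7	cg25481252	2.60e-3	open_sea	7.38	chr8	5021000	NA	FALSE	FALSE	
PCNX	cg10066683	0.0422	open_sea	5.34	chr14	5022000	31	TRUE	TRUE	
WDR35	cg13734338	0.028	open_sea	6.0	chr2	5023000	0	FALSE	TRUE	
MEGF6	cg04391135	3.50e-3	Island	6.21	chr1	5024000	0	FALSE	FALSE	
PRR5-ARHGAP8	cg06647930	0.0442	S_Shelf	4.26	chr22	5025000	NA	TRUE	FALSE	
ESYT2	cg19584649	9.36e-5	open_sea	6.66	chr7	5026000	15	TRUE	FALSE	
DHGENE1	cg90000001	0.01	open_sea	-5.0	chr1	6001000	NA	FALSE	FALSE	gwas_p
DHGENE2	cg90000002	0.01	open_sea	-4.0	chr2	6002000	NA	FALSE	FALSE	func_class
DHGENE3	cg90000003	0.01	open_sea	4.0	chr3	6003000	NA	FALSE	FALSE	consequence
DHGENE4	cg90000004	0.01	open_sea	-3.0	chr4	6004000	NA	FALSE	FALSE	cadd
DHGENE5	cg90000005	0.4	open_sea	-2.0	chr5	6005000	NA	FALSE	FALSE	dmp_not_significant
DHGENE6	cg90000006	0.01	open_sea	3.0	chr6	6006000	NA	FALSE	FALSE	cadd_boundary
DHGENE7	cg90000007	0.01	open_sea	-3.0	chr7	6007000	NA	FALSE	FALSE	gwas_p_boundary
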