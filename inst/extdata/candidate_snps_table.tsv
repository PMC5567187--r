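# Worked-example candidate SNP table: 30 risk SNPs over 26 genes for the
# FTD-ALS double-hit candidate filter, transcribed from the candidate table
# of a published blood-methylation / GWAS integration study of FTD and
# FTD-ALS. Columns gene_symbol, chromosome, strand, rsid, gwas_p, func_class,
# cadd and min_p_for_gene are as printed there.
# INTERPRETED (not printed) fields: `consequence` is stopgain for the one SNP
# the source text singles out as a stop-gain (IGHMBP2 rs201692151) and
# nonsynonymous otherwise (the text states all 30 are nonsynonymous or
# stopgain); `position` is a SYNTHETIC placeholder coordinate (the table
# prints none), constructed so that no SNP falls inside any probe's CpG
# interval, consistent with the study's statement that none colocalize.
# Rows with a nonempty `distractor_reason` are synthetic distractors, each
# violating exactly the named candidate-filter criterion; they are not part
# of the 30-row table.
gene_symbol	chromosome	strand	rsid	gwas_p	func_class	consequence	cadd	min_p_for_gene	position	distractor_reason
DLG1	chr3	-	rs74674649	6.01e-4	exonic	nonsynonymous	28.2	6.01e-4	1001000	
KIAA1147	chr7	-	rs201876806	9.13e-4	exonic	nonsynonymous	23.4	9.13e-4	1002000	
GGA1	chr22	+	rs143909159	2.91e-3	exonic	nonsynonymous	34	2.91e-3	1003000	
IGHMBP2	chr11	+	rs201692151	4.00e-3	exonic	stopgain	22.8	4.00e-3	1004000	
ASPM	chr1	-	rs150125249	5.78e-3	exonic	nonsynonymous	34	5.78e-3	1005000	
PRSS36	chr16	-	rs145749002	6.04e-3	exonic	nonsynonymous	33	6.04e-3	1006000	
CNKSR1	chr1	+	rs144396219	8.32e-3	exonic	nonsynonymous	27.7	8.32e-3	1007000	
UBTD2	chr5	-	rs17074452	9.54e-3	exonic	nonsynonymous	18.33	9.54e-3	1008000	
GGA1	chr22	+	rs138525343	9.76e-3	exonic	nonsynonymous	26.6	2.91e-3	1009000	
IGHMBP2	chr11	+	rs145226920	0.01001	exonic	nonsynonymous	35	4.00e-3	1010000	
FAH	chr15	+	rs144234072	0.01066	exonic	nonsynonymous	27.3	0.01066	1011000	
NEDD9	chr6	-	rs34044517	0.01629	exonic	nonsynonymous	23.6	5.85e-3	1012000	
BPHL	chr6	+	rs2231365	0.01671	splicing	nonsynonymous	24.1	0.01671	1013000	
ACTN3	chr11	+	rs201576110	0.02133	exonic	nonsynonymous	32	0.02133	1014000	
WDR66	chr12	+	rs77422261	0.02336	exonic	nonsynonymous	29.7	0.02336	1015000	
IQSEC1	chr3	-	rs144790333	0.02763	exonic	nonsynonymous	23	0.02763	1016000	
DLG1	chr3	-	rs141544348	0.03024	exonic	nonsynonymous	35	6.01e-4	1017000	
DUOX1	chr15	+	rs143304688	0.03047	exonic	nonsynonymous	44	0.03047	1018000	
PCDHA3	chr5	+	rs146951816	0.0354	exonic	nonsynonymous	15.16	0.0354	1019000	
C6orf70	chr6	+	rs140632188	0.04056	exonic	nonsynonymous	23	0.04056	1020000	
CLRN2	chr4	+	rs201124485	0.04711	exonic	nonsynonymous	20.6	0.04711	1021000	
COL15A1	chr9	+	rs199906142	3.62e-3	exonic	nonsynonymous	23.1	3.62e-3	1022000	
TNRC18	chr7	-	rs112785272	6.27e-3	exonic	nonsynonymous	19.2	6.27e-3	1023000	
SLC26A7	chr8	+	rs200788056	9.04e-3	exonic	nonsynonymous	23.3	9.04e-3	1024000	
PCNX	chr14	+	rs200261097	0.01309	exonic	nonsynonymous	32	0.01309	1025000	
WDR35	chr2	-	rs148436608	0.02293	exonic	nonsynonymous	16.34	0.02293	1026000	
MEGF6	chr1	-	rs61910697	0.03109	exonic	nonsynonymous	19.86	0.03109	1027000	
PRR5-ARHGAP8	chr22	+	rs55849456	0.03933	exonic	nonsynonymous	24.6	0.03933	1028000	
PRR5-ARHGAP8	chr22	+	rs16992915	0.04662	exonic	nonsynonymous	19.38	0.03933	1029000	
ESYT2	chr7	-	rs2305475	0.04728	exonic	nonsynonymous	23	0.04728	1030000	
DHGENE1	chr1	+	rs900000001	0.2	exonic	nonsynonymous	30	0.2	2001000	gwas_p
DHGENE2	chr2	+	rs900000002	0.01	intronic	none	20	0.01	2002000	func_class
DHGENE3	chr3	+	rs900000003	0.01	exonic	synonymous	30	0.01	2003000	consequence
DHGENE4	chr4	+	rs900000004	0.01	exonic	nonsynonymous	14	0.01	2004000	cadd
DHGENE5	chr5	+	rs900000005	0.01	exonic	nonsynonymous	25	0.01	2005000	dmp_not_significant
DHGENE6	chr6	+	rs900000006	0.01	exonic	nonsynonymous	15	0.01	2006000	cadd_boundary
DHGENE7	chr7	+	rs900000007	0.05	exonic	nonsynonymous	30	0.05	2007000	gwas_p_boundary
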