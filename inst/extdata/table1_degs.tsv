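gene	log2fc	fdr	alteration_pct	tumor_normal_significant	amplification_significant	oncoscore
MEPE	2.28	0.02	0.7	FALSE	FALSE	15.6
OPRPN	2.1	0.003	1.3	NA	FALSE	NA
CXCL13	2.07	0.004	1.3	TRUE	FALSE	33.7
APELA	1.87	0.0008	0.3	NA	NA	NA
CA6	1.78	0.0006	0.8	FALSE	FALSE	14.4
DIO2	1.6	0.002	0.6	FALSE	FALSE	7.7
FEZF2	1.55	0.007	0.7	TRUE	FALSE	16.1
TNNT1	1.52	0.009	2.3	FALSE	FALSE	12.3
MMP3	1.43	0.02	1.8	TRUE	FALSE	31.9
SERPINA12	1.42	0.02	0.9	TRUE	FALSE	11.9
C8B	1.42	0.03	1.8	FALSE	FALSE	7.3
KCNJ13	1.41	0.003	0.6	TRUE	FALSE	9.0
CXCL6	1.37	0.005	2.2	TRUE	FALSE	31.0
SLC12A1	1.33	0.01	0.9	TRUE	FALSE	5.6
CYP24A1	1.33	0.03	7.0	FALSE	TRUE	30.2
ASB5	1.29	0.004	1.3	FALSE	FALSE	0.0
NPY2R	1.27	0.03	1.0	TRUE	FALSE	7.9
C2CD4A	1.26	0.02	0.6	TRUE	FALSE	11.2
GABRR1	1.26	0.03	1.1	TRUE	FALSE	8.7
KIAA1210	1.25	0.007	1.6	FALSE	FALSE	0.0
MMP10	1.23	0.02	1.6	TRUE	FALSE	38.2
FAM83A	1.22	0.005	16.0	TRUE	TRUE	74.5
LPO	1.21	0.01	7.0	TRUE	TRUE	11.5
CRISP2	1.19	0.03	1.5	TRUE	TRUE	8.2
NMU	1.19	0.02	0.8	TRUE	FALSE	41.6
MAGEB4	1.18	0.009	0.8	TRUE	FALSE	55.9
MAG	1.17	0.04	2.3	TRUE	TRUE	13.2
DAPL1	1.17	0.005	0.7	FALSE	FALSE	14.0
PRSS51	1.16	0.02	1.6	NA	FALSE	NA
PBK	1.14	0.004	3.0	TRUE	FALSE	28.3
KRT77	1.13	0.04	0.8	FALSE	FALSE	0.0
CALML3	1.12	0.03	4.0	FALSE	TRUE	37.7
ACBD7	1.12	0.003	2.3	TRUE	TRUE	0.0
UNC5D	1.11	0.02	8.0	FALSE	FALSE	44.8
ESCO2	1.11	0.002	3.0	TRUE	FALSE	25.1
BARX1	1.09	0.04	5.0	TRUE	FALSE	22.3
CTXND1	1.09	0.03	0.0	NA	FALSE	NA
SYT13	1.08	0.004	1.3	TRUE	TRUE	38.8
PRAME	1.06	0.02	1.2	TRUE	FALSE	82.6
SLC39A12	1.05	0.004	2.4	FALSE	TRUE	12.0
IGHV2-26	1.04	0.04	0.1	NA	FALSE	NA
APLN	1.04	0.0007	0.6	FALSE	FALSE	13.8
IGHV3-30	1.04	0.02	0.1	NA	FALSE	48.0
LPAR3	1.04	0.008	0.9	FALSE	FALSE	12.9
ECEL1	1.03	0.02	0.8	FALSE	FALSE	NA
DCX	1.03	0.006	0.5	TRUE	FALSE	8.7
NEK2	1.02	0.007	12.0	TRUE	TRUE	61.4
CWH43	1.02	0.03	1.0	TRUE	FALSE	12.9
PRSS21	1.01	0.03	5.0	FALSE	TRUE	46.3
FOXI3	1.01	0.02	0.3	TRUE	FALSE	8.5
FCER2	-0.98	0.001	1.3	TRUE	FALSE	17.1
DACH2	-1.01	0.01	0.8	FALSE	FALSE	25.3
LILRB5	-1.02	0.0008	2.1	TRUE	FALSE	0.0
SBK3	-1.03	0.007	2.3	NA	FALSE	0.0
TRDN	-1.03	0.03	2.3	FALSE	FALSE	1.0
NXF3	-1.04	0.003	0.6	FALSE	FALSE	32.2
LILRA6	-1.05	0.002	2.1	FALSE	FALSE	0
SYNDIG1L	-1.07	0.009	0.5	NA	FALSE	0
ARPP21	-1.13	0.02	1.1	FALSE	FALSE	24.04
SLC22A12	-1.13	0.02	1.1	TRUE	FALSE	8.9
CCL24	-1.17	0.01	0.7	TRUE	FALSE	16.2
TPSD1	-1.17	0.02	5.0	TRUE	TRUE	0
PROK2	-1.19	0.02	0.7	TRUE	FALSE	18.8
HBG2	-1.59	0.04	1.0	FALSE	FALSE	11.3
FGF8	-1.68	0.0003	0.3	TRUE	FALSE	14.3
SULT1C2	-1.74	0.002	0.5	TRUE	FALSE	21.8
MS4A6E	-2.24	0.04	0.9	NA	FALSE	0
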