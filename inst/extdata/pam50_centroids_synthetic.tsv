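symbol	LumA	LumB	Her2	Basal	Normal
ACTR3B	-0.606	-0.416	-0.409	1.417	0.684
ANLN	-0.972	1.034	0.28	0.819	-0.492
BAG1	1.246	0.616	-0.112	-0.256	0.132
BCL2	1.562	0.451	0.139	-0.81	0.654
BIRC5	-0.827	0.463	0.284	0.828	-1.288
BLVRA	0.424	0.049	0.486	-0.109	-0.1
CCNB1	-1.321	0.737	0.889	1.017	-1.275
CCNE1	-1.646	0.628	-0.237	0.704	-0.692
CDC20	-1.277	0.913	0.357	0.963	-0.958
CDC6	-0.639	-0.095	0.219	0.842	-1.332
CDCA1	-0.96	0.607	0.134	0.9	-0.98
CDH3	-0.904	-0.407	-0.295	1.185	0.922
CENPF	-0.729	0.376	0.144	1.018	-0.936
CEP55	-0.745	0.784	-0.059	0.563	-1.634
CXXC5	-0.444	0.248	0.342	0.475	0.406
EGFR	-0.954	-0.056	-0.294	1.456	0.451
ERBB2	-0.398	-0.101	1.656	-0.066	-0.472
ESR1	0.954	0.874	0.203	-0.485	0.688
EXO1	-0.818	0.739	-0.248	1.087	-1.219
FGFR4	-0.273	-0.356	-0.221	-0.011	0.093
FOXA1	1.109	0.775	-0.506	-1.413	0.024
FOXC1	-1.079	-0.624	-0.389	1.189	0.037
GPR160	0.308	0.165	0.002	-0.213	0.103
GRB7	-0.537	-0.486	1.483	-0.729	-0.136
KIF2C	-1.131	0.744	0.522	0.679	-1.092
KNTC2	-1.229	0.591	0.467	1.446	-1.056
KRT14	-0.556	-0.486	0.747	1.481	0.771
KRT17	-0.367	-0.671	-0.879	1.135	0.951
KRT5	-0.591	-1.123	-0.817	1.533	0.558
MAPT	0.951	0.448	-0.561	-1.405	0.462
MDM2	2.135	0.714	-0.252	-0.762	0.612
MELK	-1.068	0.928	0.157	1.693	-0.647
MIA	-0.478	-0.812	-0.549	1.281	0.47
MKI67	-1.193	0.69	0.226	1.453	-1.174
MLPH	1.613	0.973	-0.345	-1.235	0.641
MMP11	-0.397	-0.551	-0.105	-0.304	-0.374
MYBL2	-1.328	1.244	0.647	1.187	-1.071
MYC	0.775	0.265	0.138	0.327	0.195
NAT1	1.399	0.845	-0.138	-0.44	0.334
ORC6L	-0.773	1.127	0.749	1.227	-1.028
PGR	1.619	0.587	0.421	-0.498	0.597
PHGDH	-0.657	-1.379	-0.8	1.343	0.408
PTTG1	-1.42	0.66	-0.1	0.531	-1.253
RRM2	-1.165	0.735	0.614	1.124	-0.585
SFRP1	-0.345	-0.792	-0.337	0.926	-0.336
SLC39A6	1.204	0.812	0.269	-1.082	0.184
TMEM45B	-0.02	-0.041	0.203	0.633	-0.411
TYMS	-1.249	1.07	0.503	1.214	-1.149
UBE2C	-1.556	1.298	0.134	1.168	-0.34
UBE2T	-1.231	0.357	0.441	0.617	-0.955
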