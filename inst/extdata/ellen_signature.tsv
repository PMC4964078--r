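symbol	direction
EGR1	good
FOS	good
JUN	good
RPL11	good
ZFP36	good
EEF2	good
LITAF	good
POLR2E	good
POLR3E	good
RPLP2	good
RPS15	good
RPS23	good
KIDINS220	good
PIK3R1	good
ZFP36L2	good
CDIPT	good
CXCL12	good
HLA-DPA1	good
JAK1	good
PCBP2	good
SPTBN1	good
CYFIP1	good
SGK1	good
TNFRSF10B	good
GLTSCR2	good
ITM2B	good
DUSP1	good
ABAT	good
CIRBP	good
GPX4	good
NCOR1	good
SMARCA2	good
DPYSL2	good
RAI2	good
RPL38	poor
RPS11	poor
JTB	poor
SERPINB3	poor
NUCKS1	poor
SNRPE	poor
SPDEF	poor
TXN	poor
FKBP4	poor
MTDH	poor
S100P	poor
ARF6	poor
CSTA	poor
S100G	poor
FLOT1	poor
SQLE	poor
COX5B	poor
GPR172A	poor
NAT10	poor
H3F3A	poor
ACTC1	poor
MB	poor
SFN	poor
KRT10	poor
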