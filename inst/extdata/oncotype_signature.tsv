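symbol	group	weight
GRB7	GRB7	0.9
HER2	GRB7	0.1
ER	ER	0.2
PGR	ER	0.3
BCL2	ER	0.25
SCUBE2	ER	0.25
Survivin	proliferation	0.2
Ki-67	proliferation	0.2
MYBL2	proliferation	0.2
CCNB1	proliferation	0.2
STK15	proliferation	0.2
CTSL2	invasion	0.5
MMP11	invasion	0.5
CD68	CD68	1
GSTM1	GSTM1	1
BAG1	BAG1	1
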