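alias	symbol
HER2	ERBB2
ER	ESR1
Ki-67	MKI67
KI67	MKI67
Survivin	BIRC5
STK15	AURKA
CTSL2	CTSV
CDCA1	NUF2
KNTC2	NDC80
ORC6L	ORC6
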