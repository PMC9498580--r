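# SYNTHETIC interaction edge list (STRING-export dialect:
# node node combined_score on the 0-999 scale). This file is a constructed
# stand-in for a protein-interaction database export, for examples/tests.
DNAH9	HYDIN	900
DNAH9	DNAH11	850
DNAH9	DNAI1	800
DNAH11	DNAI1	820
DNAI1	SPAG17	800
SPAG17	HYDIN	750
DNAH9	DNAH3	600
DNAH9	WDR63	500
DNAH3	WDR63	600
DNAH9	CFAP70	550
CFAP43	WDR63	700
CFAP43	CFAP70	600
TRAF3IP1	IFT46	700
OFD1	PIBF1	700
OFD1	DNAH11	150
OFD1	BBS7	600
BBS7	PIBF1	550
TRAF3IP1	OFD1	500
IFT46	OFD1	450
TTC25	DNAH9	600
TTC25	DNAI1	650
CCDC113	TTC25	700
MNS1	DNAH9	400
CFAP100	CFAP77	500
KMT2D	KDM6A	900
MEGF8	NODAL	400
ARMC9	CEP295	450
TTLL6	SPAG17	300
MORN3	MORN1	350
TRPV4	IFT46	200
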