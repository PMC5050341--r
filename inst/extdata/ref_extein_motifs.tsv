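family	label	start	end
TerL1	walker_A	61	68
TerL1	walker_B	141	146
TerL1	c_motif	201	206
TerL6	walker_A	55	62
TerL6	walker_B	131	136
TerL6	c_motif	191	196
Pham3880	c_motif	71	78
RecB	pd_dexk	121	129
RDF	metallophos	91	100
TOPRIM	active_site	111	118
NT	active_site	101	107
DNMT1	active_site	95	102
DNMT2	active_site	90	97
PORT	other	150	158
HEL	walker_A	71	78
TdS	active_site	106	112
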