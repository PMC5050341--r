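family	ref_column	plus_one
TerL1	67	T
TerL1	68	S
TerL1	143	T
TerL1	150	C
TerL1	170	C
TerL6	193	C
Pham3880	74	C
RecB	124	C
RDF	95	C
TOPRIM	114	C
NT	103	C
DNMT1	98	C
DNMT2	93	C
PORT	153	C
HEL	74	S
TdS	109	C
TdS	160	C
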