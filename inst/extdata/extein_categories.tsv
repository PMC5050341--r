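family	category
TerL1	nucleic_acid_binding
TerL6	nucleic_acid_binding
Pham3880	nucleic_acid_binding
RecB	nucleic_acid_binding
RDF	nucleic_acid_binding
TOPRIM	nucleic_acid_binding
NT	nucleic_acid_binding
DNMT1	nucleic_acid_binding
DNMT2	nucleic_acid_binding
PORT	nucleic_acid_binding
HEL	nucleic_acid_binding
TdS	nucleic_acid_binding
TerL1	hydrolase
TerL6	hydrolase
Pham3880	hydrolase
RecB	hydrolase
RDF	hydrolase
HEL	hydrolase
PORT	hydrolase
NT	transferase
DNMT1	transferase
DNMT2	transferase
TOPRIM	transferase
TdS	transferase
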