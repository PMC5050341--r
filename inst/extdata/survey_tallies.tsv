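cluster	n_total	n_positive
C	62	55
B	145	6
Other	634	100
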