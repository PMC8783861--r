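population	group_a	group_b	fc
Treg cells	ALK	NEG	2.1
Treg cells	ALK	EGFR	1.9
Cytotoxic cells	EGFR	NEG	-2.1
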