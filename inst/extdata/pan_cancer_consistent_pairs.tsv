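gene_a	gene_b	category
ADH6	GYC1	neg_less_neg
ADPGK	SLC2A4	neg_less_neg
ENO1	PPP2R1A	pos_less_pos
MDH2	SLC25A11	pos_less_pos
PGM2	PPP2CA	pos_less_pos
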