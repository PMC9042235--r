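chain_a	res_a	chain_b	res_b	class	probability	upper_bound
A	44	E	46	crosslink_positive		12
A	135	E	46	crosslink_positive		12
A	231	S	97	crosslink_positive		12
A	44	S	20	crosslink_positive		12
A	44	S	24	crosslink_positive		12
A	70	S	18	crosslink_positive		12
A	70	S	24	crosslink_positive		12
A	214	S	41	crosslink_positive		12
A	70	E	46	crosslink_negative		12
A	44	S	18	crosslink_negative		12
A	44	S	21	crosslink_negative		12
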