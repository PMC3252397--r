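locus	pos35	pos10	spacer_len
Afe_1009	52	70	12
Afe_1437	50	71	15
Afe_2172	23	44	15
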