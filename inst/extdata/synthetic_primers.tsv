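gene	forward	reverse	expected_amplicon_bp
Afe_1009	CCGAAATACCTGAGGTCAA	TCCCTTTCTCCTCCTTCTCC	91
Afe_1437	GTATTGAAGGCGGAGATTGC	TCTTCTTCCTTGACGCCACT	118
Afe_2172	AGGTAATCTTCAGCGGCAAC	TAGGGGATCTCCAGACGATG	97
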