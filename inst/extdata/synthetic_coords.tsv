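locus	replicon	start	end	strand
Afe_1009	synthetic_chr	261	698	+
Afe_1437	synthetic_chr	959	1405	+
Afe_2172	synthetic_chr	1406	1810	-
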