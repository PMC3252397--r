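site35	spacer_len	site10
CTTGAA	13	CCCCATAA
ATTGAT	13	CCCCATAT
CTTGAA	15	CCCCATAT
CTTGAA	15	CCCCATCT
CGTGGA	15	CCCCATAT
CCCGAA	14	CCCCATAT
CCTGAA	14	CCCCATAT
CTTGAA	15	CCAGATAT
CTTGAA	15	GCCCCTAT
CTTCAA	11	CCCCCTAC
CTTGAA	13	CCCCATTT
CTTTAA	14	CCCAATGT
CTGGAA	15	CCCCATAT
CTTGAA	12	CCCCATAT
CTGGAA	12	CCCCTTAT
CTTGCA	11	CCCCATGT
ATTCAA	14	CCCCATAT
CTTGAT	15	TCCCTTAT
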