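>Afe_1009
MFSSFMYHLIPKYLRSSVTDAICEVVCYPSLPHMEKEEKGSLEMGSYGFAQKPSFASSRN
ICRFANNPNTGGGQVCTIWARPLLIPYLIYIYRSNWSYRGPRIWVRCSLQHAAYITLFNA
GHFIKSTSVQHCLSPHRLFNCLLLR
>Afe_1437
MRLRSTYIEDVLKAEIAACQIREYMMINNDFSCNVSIFTALGLVASRKKSTVLESHPEIS
SCVCLLGTYPVLSGMTLYAIRPFNSRTHIGQIRRPVICNIHRHVDGSQLILNGACIRKRT
EPRCSVDVRYLTHSYARADASKGIERST
>Afe_2172
MRRRMDITGVEVIFSGNPRLANCRRLAVLTTGAWSAHRLEIPYCRPPTISTYDKRAGRLT
SGAVPRWAARAPDQSTLPSAEVSGQAATCEYSTRPFVFRRHVTPVTIALDKARDKIYLTC
RRQTARRPNGLILI
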