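gene	condition	replicate	ct
Afe_1009	control_30C	1	20.6867
Afe_1009	control_30C	2	20.5621
Afe_1009	control_30C	3	21.0456
Afe_1009	hs_15min	1	20.6538
Afe_1009	hs_15min	2	20.2058
Afe_1009	hs_15min	3	20.8612
Afe_1009	hs_30min	1	19.8525
Afe_1009	hs_30min	2	19.8764
Afe_1009	hs_30min	3	19.7881
Afe_1009	hs_60min	1	19.3758
Afe_1009	hs_60min	2	18.8635
Afe_1009	hs_60min	3	19.0398
Afe_1437	control_30C	1	21.1927
Afe_1437	control_30C	2	20.9348
Afe_1437	control_30C	3	20.9655
Afe_1437	hs_15min	1	18.3655
Afe_1437	hs_15min	2	18.5620
Afe_1437	hs_15min	3	18.5650
Afe_1437	hs_30min	1	16.5576
Afe_1437	hs_30min	2	16.9365
Afe_1437	hs_30min	3	16.4831
Afe_1437	hs_60min	1	16.0512
Afe_1437	hs_60min	2	15.8372
Afe_1437	hs_60min	3	15.3454
Afe_2172	control_30C	1	20.9952
Afe_2172	control_30C	2	21.4170
Afe_2172	control_30C	3	21.2784
Afe_2172	hs_15min	1	20.7768
Afe_2172	hs_15min	2	20.3191
Afe_2172	hs_15min	3	20.4156
Afe_2172	hs_30min	1	20.1533
Afe_2172	hs_30min	2	20.3191
Afe_2172	hs_30min	3	20.1734
Afe_2172	hs_60min	1	20.0315
Afe_2172	hs_60min	2	19.8893
Afe_2172	hs_60min	3	19.9763
alaS	control_30C	1	16.5243
alaS	control_30C	2	15.9659
alaS	control_30C	3	15.5788
alaS	hs_15min	1	15.9715
alaS	hs_15min	2	15.7745
alaS	hs_15min	3	15.9953
alaS	hs_30min	1	16.5484
alaS	hs_30min	2	16.1801
alaS	hs_30min	3	15.9280
alaS	hs_60min	1	16.1207
alaS	hs_60min	2	16.1107
alaS	hs_60min	3	15.8734
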