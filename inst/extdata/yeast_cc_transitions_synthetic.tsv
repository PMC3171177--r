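Cln3_in	MBF_in	SBF_in	Cln12_in	Cdh1_in	Swi5_in	Cdc20_14_in	Clb56_in	Sic1_in	Clb12_in	Mcm1_in	Cln3_out	MBF_out	SBF_out	Cln12_out	Cdh1_out	Swi5_out	Cdc20_14_out	Clb56_out	Sic1_out	Clb12_out	Mcm1_out
1	0	0	0	1	0	0	0	1	0	0	0	1	1	0	1	0	0	0	1	0	0
0	1	1	0	1	0	0	0	1	0	0	0	1	1	1	1	0	0	0	1	0	0
0	1	1	1	1	0	0	0	1	0	0	0	1	1	1	0	0	0	0	0	0	0
0	1	1	1	0	0	0	0	0	0	0	0	1	1	1	0	0	0	1	0	0	0
0	1	1	1	0	0	0	1	0	0	0	0	1	1	1	0	0	0	1	0	1	1
0	1	1	1	0	0	0	1	0	1	1	0	0	0	1	0	0	1	1	0	1	1
0	0	0	1	0	0	1	1	0	1	1	0	0	0	0	0	1	1	0	0	1	1
0	0	0	0	0	1	1	0	0	1	1	0	0	0	0	0	1	1	0	1	1	1
0	0	0	0	0	1	1	0	1	1	1	0	0	0	0	0	1	1	0	1	0	1
0	0	0	0	0	1	1	0	1	0	1	0	0	0	0	1	1	1	0	1	0	0
0	0	0	0	1	1	1	0	1	0	0	0	0	0	0	1	1	0	0	1	0	0
0	0	0	0	1	1	0	0	1	0	0	0	0	0	0	1	0	0	0	1	0	0
0	0	1	0	0	0	1	1	1	0	0	0	0	1	1	0	1	0	0	1	0	1
0	0	1	1	0	1	0	0	1	0	1	0	0	1	1	0	1	1	0	1	0	0
0	0	1	1	0	1	1	0	1	0	0	0	0	1	1	0	1	0	0	1	0	0
0	0	1	1	0	1	0	0	1	0	0	0	0	1	1	0	0	0	0	1	0	0
0	0	1	1	0	0	0	0	1	0	0	0	0	1	1	0	0	0	0	0	0	0
0	0	1	1	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0
0	1	0	1	0	0	1	0	1	0	0	0	1	0	0	0	1	0	0	1	0	0
0	1	0	0	0	1	0	0	1	0	0	0	1	0	0	0	0	0	0	1	0	0
0	1	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	1	0	0
0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
0	1	0	0	1	0	0	0	0	0	1	0	1	0	0	1	1	1	1	0	0	0
0	1	0	0	1	1	1	1	0	0	0	0	1	0	0	1	1	0	1	1	0	1
0	1	0	0	1	1	0	1	1	0	1	0	1	0	0	0	1	1	1	1	0	1
0	1	0	0	0	1	1	1	1	0	1	0	1	0	0	0	1	1	0	1	0	1
0	1	0	0	0	1	1	0	1	0	1	0	1	0	0	1	1	1	0	1	0	0
0	1	0	0	1	1	1	0	1	0	0	0	1	0	0	1	1	0	0	1	0	0
0	1	0	0	1	1	0	0	1	0	0	0	1	0	0	1	0	0	0	1	0	0
0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0
0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
1	0	0	0	1	0	1	1	0	0	0	0	1	1	0	1	1	0	0	0	0	1
0	1	1	0	1	1	0	0	0	0	1	0	1	1	1	1	1	1	1	1	0	0
0	1	1	1	1	1	1	1	1	0	0	0	1	1	1	0	1	0	0	1	0	1
0	1	1	1	0	1	0	0	1	0	1	0	1	1	1	0	1	1	0	1	0	0
0	1	1	1	0	1	1	0	1	0	0	0	1	1	1	0	1	0	0	1	0	0
0	1	1	1	0	1	0	0	1	0	0	0	1	1	1	0	0	0	0	1	0	0
0	1	1	1	0	0	0	0	1	0	0	0	1	1	1	0	0	0	0	0	0	0
1	1	0	0	1	0	1	1	0	0	1	0	1	1	0	1	1	1	1	0	0	1
0	1	1	0	1	1	1	1	0	0	1	0	1	1	1	1	1	1	1	1	0	1
0	1	1	1	1	1	1	1	1	0	1	0	1	1	1	0	1	1	0	1	0	1
0	1	1	1	0	1	1	0	1	0	1	0	1	1	1	0	1	1	0	1	0	0
1	1	0	0	1	1	1	1	0	0	0	0	1	1	0	1	1	0	1	1	0	1
0	1	1	0	1	1	0	1	1	0	1	0	1	1	1	0	1	1	1	1	0	1
0	1	1	1	0	1	1	1	1	0	1	0	1	1	1	0	1	1	0	1	0	1
1	1	0	0	1	1	0	0	0	0	1	0	1	1	0	1	1	1	1	1	0	0
0	1	1	0	1	1	1	1	1	0	0	0	1	1	1	1	1	0	0	1	0	1
0	1	1	1	1	1	0	0	1	0	1	0	1	1	1	0	1	1	0	1	0	0
1	1	0	0	1	1	0	1	1	0	1	0	1	1	0	0	1	1	1	1	0	1
0	1	1	0	0	1	1	1	1	0	1	0	1	1	1	0	1	1	0	1	0	1
1	1	0	0	1	1	1	1	0	0	1	0	1	1	0	1	1	1	1	1	0	1
0	1	1	0	1	1	1	1	1	0	1	0	1	1	1	1	1	1	0	1	0	1
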