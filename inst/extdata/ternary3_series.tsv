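x1	x2	x3
2	1	0
1	2	0
2	1	1
0	0	1
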