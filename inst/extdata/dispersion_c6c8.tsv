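elemA	elemB	C6	C8
H	H	6.5	39
H	C	17.404	138.1401
H	N	12.5419	92.164
H	O	10.0698	68.8877
H	S	29.5127	285.5269
H	F	7.8581	50.5613
H	Cl	24.7972	225.6407
H	Br	32.45	325.795
H	I	50.025	553.4492
H	Zn	42.9651	390.9588
C	C	46.6	489.3
C	N	33.5815	326.4499
C	O	26.9622	244.0041
C	S	79.0215	1011.3519
C	F	21.0404	179.0911
C	Cl	66.3955	799.2317
C	Br	86.8861	1153.9839
C	I	133.944	1960.3475
C	Zn	115.0409	1384.7977
N	N	24.2	217.8
N	O	19.4299	162.7941
N	S	56.9456	674.7512
N	F	15.1625	119.4855
N	Cl	47.8468	533.2294
N	Br	62.6131	769.912
N	I	96.5246	1307.8995
N	Zn	82.9024	923.9057
O	O	15.6	121.68
O	S	45.7209	504.341
O	F	12.1737	89.3091
O	Cl	38.4156	398.5609
O	Br	50.2713	575.4688
O	I	77.4984	977.5862
O	Zn	66.5612	690.571
S	S	134	2090.4
S	F	35.6791	370.1699
S	Cl	112.5895	1651.9611
S	Br	147.3363	2385.2112
S	I	227.1343	4051.9133
S	Zn	195.0795	2862.2885
F	F	9.5	65.55
F	Cl	29.9783	292.5307
F	Br	39.2301	422.3753
F	I	60.4773	717.5163
F	Zn	51.9423	506.8565
Cl	Cl	94.6	1305.48
Cl	Br	123.795	1884.9388
Cl	I	190.8429	3202.0681
Cl	Zn	163.9097	2261.9543
Br	Br	162	2721.6
Br	I	249.7399	4623.3588
Br	Zn	214.4948	3265.96
I	I	385	7854
I	Zn	330.666	5548.0985
Zn	Zn	284	3919.2
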