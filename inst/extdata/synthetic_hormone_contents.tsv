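hormone	time	content
GA3	0	4.39
GA3	2	9.20
GA3	4	15.10
GA3	8	20.50
GA3	16	26.34
ABA	0	77.62
ABA	2	70.10
ABA	4	94.34
ABA	8	108.00
ABA	16	120.24
IAA	0	95.85
IAA	2	49.37
IAA	4	64.41
IAA	8	70.90
IAA	16	77.82
JA	0	13.31
JA	2	21.40
JA	4	37.32
JA	8	30.10
JA	16	24.60
ZR	0	10.21
ZR	2	5.35
ZR	4	7.07
ZR	8	7.85
ZR	16	8.36
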