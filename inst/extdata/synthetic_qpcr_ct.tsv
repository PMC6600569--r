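gene	condition	replicate	ct
GA20ox	0h	1	27.10
GA20ox	0h	2	27.30
GA20ox	0h	3	27.20
GA20ox	2h	1	25.40
GA20ox	2h	2	25.60
GA20ox	2h	3	25.50
GA20ox	4h	1	23.90
GA20ox	4h	2	24.10
GA20ox	4h	3	24.00
NCED3	0h	1	24.50
NCED3	0h	2	24.70
NCED3	0h	3	24.60
NCED3	2h	1	25.80
NCED3	2h	2	26.00
NCED3	2h	3	25.90
NCED3	4h	1	26.90
NCED3	4h	2	27.10
NCED3	4h	3	27.00
TIP1	0h	1	20.00
TIP1	0h	2	20.20
TIP1	0h	3	20.10
TIP1	2h	1	20.10
TIP1	2h	2	20.30
TIP1	2h	3	20.20
TIP1	4h	1	19.90
TIP1	4h	2	20.10
TIP1	4h	3	20.00
GAPDH	0h	1	18.50
GAPDH	0h	2	18.70
GAPDH	0h	3	18.60
GAPDH	2h	1	18.60
GAPDH	2h	2	18.80
GAPDH	2h	3	18.70
GAPDH	4h	1	18.40
GAPDH	4h	2	18.60
GAPDH	4h	3	18.50
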