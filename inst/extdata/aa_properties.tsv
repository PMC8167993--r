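residue	hydrophobicity	hydrophilicity	volume	polarity	polarizability	sasa
A	0.62	-0.5	27.5	8.1	0.046	1.181
C	0.29	-1.0	44.6	5.5	0.128	1.461
D	-0.90	3.0	40.0	13.0	0.105	1.587
E	-0.74	3.0	62.0	12.3	0.151	1.862
F	1.19	-2.5	115.5	5.2	0.290	2.228
G	0.48	0.0	0.0	9.0	0.000	0.881
H	-0.40	-0.5	79.0	10.4	0.230	2.025
I	1.38	-1.8	93.5	5.2	0.186	1.810
K	-1.50	3.0	100.0	11.3	0.219	2.258
L	1.06	-1.8	93.5	4.9	0.186	1.931
M	0.64	-1.3	94.1	5.7	0.221	2.034
N	-0.78	0.2	58.7	11.6	0.134	1.655
P	0.12	0.0	41.9	8.0	0.131	1.468
Q	-0.85	0.2	80.7	10.5	0.180	1.932
R	-2.53	3.0	105.0	10.5	0.291	2.560
S	-0.18	0.3	29.3	9.2	0.062	1.298
T	-0.05	-0.4	51.3	8.6	0.108	1.525
V	1.08	-1.5	71.5	5.9	0.140	1.645
W	0.81	-3.4	145.5	5.4	0.409	2.663
Y	0.26	-2.3	117.3	6.2	0.298	2.368
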