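rank	metabolite	p_omnibus	q_reported
1	Lysophosphatidylcholine a C18:0	1.19E-08	5.48E-06
2	Hypoxanthine	9.03E-08	2.08E-05
3	Lysophosphatidylcholine a C16:0	2.75E-07	4.23E-05
4	Lysophosphatidylcholine a C18:1	1.56E-06	0.000180053
5	Lysophosphatidylcholine a C17:0	1.71E-05	0.001580532
6	Ceramide (d18:2/24:0)	2.14E-05	0.001643773
7	Ceramide (d16:1/24:0)	3.39E-05	0.002231623
8	Lysophosphatidylcholine a C18:2	7.64E-05	0.004403035
9	Phosphatidylcholine aa C32:2	0.000143795	0.007365506
10	Ceramide (d16:1/23:0)	0.000210124	0.009686713
11	Ceramide (d18:1/24:0)	0.000452942	0.017414705
12	Ceramide (d16:1/22:0)	0.000453311	0.017414705
13	Lysophosphatidylcholine a C24:0	0.000632704	0.02099238
14	Glycine	0.000637513	0.02099238
15	Phosphatidylcholine ae C44:3	0.000728012	0.022374244
16	Ceramide (d18:2/22:0)	0.000949566	0.027359369
17	Phosphatidylcholine ae C40:1	0.001443081	0.03913296
18	Phosphatidylcholine ae C42:1	0.001912612	0.048984116
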