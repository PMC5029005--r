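# text = About 450 mg of FB1 were obtained from 800 g cultured corn.
1	About	2	quantmod
2	450	3	num
3	mg	7	nsubjpass
4	of	3	prep
5	FB1	4	pobj
6	were	7	auxpass
7	obtained	0	root
8	from	7	prep
9	800	10	num
10	g	12	nn
11	cultured	12	amod
12	corn	8	pobj
13	.	7	punct

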