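# Synthetic, illustrative cytogenetic band weights for the simulator.
# Weights are loosely patterned after relative gene densities of the
# human karyotype; they are NOT measured hg19 gene densities.
chromosome	subband	weight
1	1p36.1	28
1	1p34.2	24
1	1q21.3	26
1	1q42.1	22
2	2p23.3	20
2	2q31.1	20
2	2q37.1	19
3	3p21.3	26
3	3q26.1	22
4	4q13.3	16
4	4q28.2	14
5	5q13.2	18
5	5q31.1	20
6	6p21.3	30
6	6q22.1	16
7	7p15.2	18
7	7q22.1	22
8	8p11.2	14
8	8q24.1	16
9	9p13.3	16
9	9q34.1	20
10	10q22.1	16
10	10q24.2	16
11	11p15.5	24
11	11q13.1	26
11	11q23.3	18
12	12p13.3	20
12	12q13.2	24
13	13q14.2	12
13	13q34	10
14	14q11.2	16
14	14q32.3	18
15	15q15.1	14
15	15q24.1	14
16	16p13.3	24
16	16p11.2	20
16	16q22.1	20
17	17p13.1	24
17	17q21.3	28
17	17q25.3	20
18	18q12.1	8
18	18q21.3	10
19	19p13.3	30
19	19p13.1	22
19	19q13.1	24
19	19q13.2	15
19	19q13.3	28
19	19q13.4	18
20	20q11.2	18
20	20q13.1	16
21	21q22.1	10
21	21q22.3	10
22	22q11.2	18
22	22q13.1	16
X	Xp11.2	14
X	Xq28	16
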