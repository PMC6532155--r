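chrom	n_snps	mean_distance_kbp
1	10228	19.21
2	7077	21.14
3	5196	21.44
4	4589	19.91
5	2705	22.10
6	1750	20.36
7	1684	21.63
8	1314	22.81
9	1236	18.98
10	1399	14.59
11	1373	14.67
12	1389	14.34
13	1041	17.67
14	1118	14.43
15	761	16.71
16	81	7.37
17	724	14.31
18	736	14.94
19	725	13.74
20	867	16.04
21	503	13.53
22	153	30.00
23	321	17.76
24	390	15.98
25	106	26.67
26	339	15.36
27	277	20.22
28	317	15.91
Z	3785	21.67
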