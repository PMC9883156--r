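##fileformat=VCFv4.2
##source=gpdscan
##INFO=<ID=AF,Number=A,Type=Float,Description="Nominal alt allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I00001	I00002	I00003	I00004	I00005	I00006	I00007	I00008	I00009	I00010	I00011	I00012	I00013	I00014	I00015	I00016	I00017	I00018	I00019	I00020	I00021	I00022	I00023	I00024	I00025	I00026	I00027	I00028	I00029	I00030
1	100000	v1_100000	A	G	.	PASS	AF=0.627194	GT	0|0	0|1	1|0	1|0	1|1	1|1	0|1	0|0	1|0	1|0	1|0	1|0	1|0	1|0	0|0	0|1	1|1	1|1	0|1	0|0	1|1	0|1	0|1	0|0	1|1	1|1	1|1	1|0	0|1	1|1
1	200000	v1_200000	A	G	.	PASS	AF=0.277828	GT	1|0	1|0	0|1	0|0	0|1	0|1	1|0	1|0	0|1	0|1	0|0	0|0	1|0	1|0	0|0	0|0	1|1	1|1	0|1	0|1	0|1	0|1	0|1	0|1	0|0	0|1	0|0	0|0	0|1	0|1
2	100000	v2_100000	A	G	.	PASS	AF=0.577047	GT	1|1	0|1	1|0	1|1	1|1	0|1	1|0	1|0	1|1	1|1	1|1	1|0	0|1	0|0	0|1	0|0	0|0	0|0	0|0	1|0	0|1	0|1	1|0	1|0	1|0	1|1	1|0	1|0	1|1	1|1
2	200000	v2_200000	A	G	.	PASS	AF=0.497288	GT	1|1	1|0	1|1	0|1	1|1	0|1	0|0	0|0	0|1	0|1	1|1	0|1	0|1	1|1	0|1	1|1	1|1	0|1	1|0	1|0	0|0	0|0	1|1	1|1	0|1	1|1	1|1	1|0	1|1	1|1
3	100000	v3_100000	A	G	.	PASS	AF=0.72714	GT	1|0	1|1	1|0	1|1	1|0	1|0	1|0	1|1	0|1	0|1	1|1	1|1	1|0	1|1	1|1	1|0	0|1	0|1	1|0	1|0	1|1	1|0	1|1	1|1	1|0	1|0	0|1	0|1	1|1	0|1
3	200000	v3_200000	A	G	.	PASS	AF=0.323224	GT	0|0	0|0	0|0	1|0	0|1	0|1	0|1	1|1	1|1	1|1	1|1	1|1	0|0	0|0	0|0	0|0	0|0	0|1	0|0	1|0	0|0	0|0	0|0	0|0	0|1	0|1	0|1	0|0	0|0	0|0
4	100000	v4_100000	A	G	.	PASS	AF=0.776596	GT	1|1	1|1	0|1	1|1	1|0	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	0|0	0|0	1|1	0|1	0|0	0|1	1|1	1|1	0|1	1|1	1|0	1|1	0|1	0|1
4	200000	v4_200000	A	G	.	PASS	AF=0.749163	GT	1|1	1|1	1|1	1|1	0|1	0|1	1|1	1|1	1|1	1|1	1|1	1|1	0|1	1|1	1|1	1|1	0|1	0|1	1|1	1|1	1|1	1|1	0|1	0|1	0|1	0|1	0|1	0|1	1|1	1|1
5	100000	v5_100000	A	G	.	PASS	AF=0.292712	GT	0|0	0|0	1|0	1|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	1|0	0|1	0|1	0|0	0|0	1|0	1|0	0|0	0|0	1|1	0|1	1|0	1|0	0|1	0|0
5	200000	v5_200000	A	G	.	PASS	AF=0.645235	GT	0|1	0|1	1|1	1|1	1|0	1|1	1|1	1|0	1|1	1|1	1|1	0|1	1|1	1|1	1|1	0|1	1|0	1|0	1|1	1|1	0|0	0|0	1|0	1|0	0|0	0|0	1|1	0|0	1|0	0|0
6	100000	v6_100000	A	G	.	PASS	AF=0.643295	GT	1|1	1|0	1|1	0|1	1|1	1|1	1|1	0|1	0|1	0|1	1|0	0|0	0|1	0|1	0|1	0|1	1|0	1|0	1|1	1|1	0|1	0|0	0|1	0|0	1|0	1|0	1|0	1|0	1|1	1|0
6	200000	v6_200000	A	G	.	PASS	AF=0.512888	GT	1|0	1|0	0|1	0|0	0|1	1|0	1|0	1|1	0|1	0|1	0|0	1|0	1|1	1|1	0|0	1|0	1|0	1|0	1|1	1|1	1|1	0|1	0|0	0|0	0|0	0|0	1|1	1|1	1|1	1|0
7	100000	v7_100000	A	G	.	PASS	AF=0.558162	GT	1|1	1|1	0|1	1|1	1|0	1|0	0|0	0|0	1|1	1|0	1|0	1|0	1|0	1|0	0|0	0|1	1|0	1|1	0|1	0|1	0|0	1|0	0|1	0|1	1|1	0|1	1|0	1|0	1|1	0|1
7	200000	v7_200000	A	G	.	PASS	AF=0.797172	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	0|1	0|1	1|1	1|1	1|1	1|1	1|1	0|1	0|1	0|1	0|1	0|1	1|0	0|0	1|0	1|0	1|0	1|0
8	100000	v8_100000	A	G	.	PASS	AF=0.416771	GT	0|0	0|0	0|1	0|1	1|0	1|0	0|1	0|1	0|0	1|0	0|0	0|0	0|1	0|1	1|1	1|0	1|0	0|0	0|0	1|1	0|0	0|0	1|0	0|0	1|0	1|0	0|0	1|0	0|0	0|1
8	200000	v8_200000	A	G	.	PASS	AF=0.20834	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|1	0|0	0|0	0|0	0|0	0|0	1|0	1|0	1|0	1|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	1|0	0|0	0|0	0|0	0|0
9	100000	v9_100000	A	G	.	PASS	AF=0.657349	GT	1|1	1|0	1|1	1|1	1|1	0|1	1|0	1|0	1|1	0|1	0|1	1|1	1|1	0|1	0|0	0|1	1|1	1|1	1|1	1|1	0|1	1|1	1|1	0|1	0|0	0|0	1|0	1|0	1|0	1|0
9	200000	v9_200000	A	G	.	PASS	AF=0.622702	GT	1|0	1|0	1|1	1|0	0|1	1|1	1|1	1|1	1|0	1|0	1|0	0|0	1|1	1|0	1|1	1|0	1|1	0|1	1|0	0|1	1|1	1|1	0|1	0|1	1|1	1|1	1|0	1|1	0|0	1|1
10	100000	v10_100000	A	G	.	PASS	AF=0.699429	GT	1|1	1|1	0|1	0|0	1|1	0|1	1|0	1|1	1|1	1|0	1|0	1|1	1|1	1|1	0|1	0|1	1|0	1|1	0|1	1|1	1|0	1|0	1|1	1|1	1|1	1|1	0|1	1|1	0|0	1|0
10	200000	v10_200000	A	G	.	PASS	AF=0.709536	GT	1|0	0|0	1|0	0|0	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	0|1	1|0	1|1	1|1	1|0	1|0	1|1	1|1	1|1	1|1	1|1	1|1	0|1	0|1
11	100000	v11_100000	A	G	.	PASS	AF=0.648356	GT	1|1	1|1	1|0	1|1	0|0	0|1	1|1	1|1	1|0	1|0	1|1	1|1	1|0	1|0	1|0	1|0	1|1	1|1	0|1	0|1	1|1	1|1	1|1	1|1	0|1	1|1	1|0	1|1	1|0	1|0
11	200000	v11_200000	A	G	.	PASS	AF=0.323661	GT	1|0	1|0	1|0	1|0	0|0	1|0	1|0	0|0	0|0	0|0	1|1	1|0	0|0	0|0	1|0	1|0	0|0	0|0	1|0	1|0	0|0	0|0	0|1	1|0	0|0	0|0	0|0	0|0	0|1	0|1
12	100000	v12_100000	A	G	.	PASS	AF=0.618842	GT	1|0	0|0	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|0	0|0	1|1	0|0	0|0	0|1	1|1	1|0	1|1	0|1	0|1	1|0	1|0	0|0	0|0	1|1	1|1	0|1	0|1	0|1	0|1
12	200000	v12_200000	A	G	.	PASS	AF=0.269368	GT	0|0	0|0	0|0	0|0	0|0	0|0	1|1	1|1	1|1	1|1	0|0	1|0	0|0	0|0	1|0	0|0	1|0	1|0	0|0	0|1	0|0	0|0	0|1	0|0	0|1	0|0	0|0	0|1	1|1	0|1
13	100000	v13_100000	A	G	.	PASS	AF=0.696198	GT	1|0	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	0|1	1|1	0|1	1|1	1|1	1|1	0|1	1|1	1|1	0|1	1|1	1|1	0|1	1|1
13	200000	v13_200000	A	G	.	PASS	AF=0.680464	GT	1|0	1|0	1|1	1|1	1|1	1|1	0|1	0|1	1|1	1|0	1|1	1|1	0|1	0|1	1|1	1|1	0|1	0|1	0|1	0|1	0|1	1|1	1|1	1|1	1|1	1|1	1|0	1|1	1|1	1|0
14	100000	v14_100000	A	G	.	PASS	AF=0.497228	GT	1|0	0|1	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	0|0	0|0	0|0	0|1	0|1	0|0	0|1	1|1	0|1	0|1	0|0	0|1	1|0	1|0	0|0	0|0	0|1	0|1
14	200000	v14_200000	A	G	.	PASS	AF=0.662088	GT	0|0	0|0	1|1	1|0	0|0	1|1	1|1	1|1	0|1	0|1	0|0	0|1	0|0	0|0	1|1	1|1	1|1	1|1	1|1	1|1	0|1	1|1	1|1	1|1	1|1	1|0	0|0	0|0	0|1	0|0
15	100000	v15_100000	A	G	.	PASS	AF=0.549233	GT	1|1	1|1	1|1	1|1	1|0	0|0	0|0	0|0	1|1	1|1	1|1	0|0	0|1	0|1	0|1	0|0	0|0	0|0	0|1	1|1	1|1	1|1	0|0	0|0	1|1	1|0	1|0	1|0	0|1	1|0
15	200000	v15_200000	A	G	.	PASS	AF=0.698565	GT	1|1	1|1	1|1	1|0	0|1	0|1	0|1	0|1	1|1	1|1	0|1	0|1	1|1	1|1	0|1	1|1	1|1	1|0	1|0	1|0	1|0	1|0	0|0	1|0	1|1	1|1	1|1	1|1	1|1	0|1
16	100000	v16_100000	A	G	.	PASS	AF=0.784306	GT	1|1	1|1	1|0	1|1	1|1	1|1	1|1	1|1	1|1	1|0	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|0	0|1	0|1	1|1	1|1	1|0	1|1
16	200000	v16_200000	A	G	.	PASS	AF=0.624594	GT	1|1	1|1	1|1	0|1	1|1	1|1	0|1	0|1	0|0	0|0	1|1	0|1	0|0	0|0	1|1	1|0	1|0	1|0	1|1	1|1	1|0	1|0	1|1	1|1	0|0	0|1	0|1	0|0	1|0	0|0
17	100000	v17_100000	A	G	.	PASS	AF=0.451564	GT	0|1	0|1	1|0	1|1	1|1	0|0	1|1	1|0	0|1	0|1	1|1	1|1	0|0	0|0	0|1	0|1	0|0	0|1	1|0	1|0	1|1	0|1	1|0	1|0	0|0	0|1	1|1	0|1	1|0	1|0
17	200000	v17_200000	A	G	.	PASS	AF=0.361622	GT	1|0	1|0	1|0	0|0	0|1	0|1	0|0	0|0	1|1	0|1	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0	1|0	1|1	0|0	0|0	0|1	0|0	0|0	0|0	0|1	0|1	1|1	1|1
18	100000	v18_100000	A	G	.	PASS	AF=0.648059	GT	1|1	1|0	0|1	0|0	1|1	1|1	0|1	1|1	0|1	0|1	1|0	0|1	0|1	0|0	0|1	1|1	0|0	1|0	0|1	1|0	0|0	0|1	0|1	1|0	0|0	0|1	1|1	0|1	1|0	1|0
18	200000	v18_200000	A	G	.	PASS	AF=0.751426	GT	1|1	1|1	0|1	1|1	1|1	1|1	1|0	0|0	0|0	1|0	1|1	1|0	1|1	1|1	1|1	0|1	1|1	1|1	1|1	1|1	1|1	1|0	1|1	1|1	1|1	1|1	0|1	1|1	1|1	1|1
19	100000	v19_100000	A	G	.	PASS	AF=0.320278	GT	1|1	1|1	1|1	0|0	0|0	0|1	1|0	1|0	0|0	0|0	1|0	1|0	0|0	0|0	0|0	0|0	0|1	0|0	0|1	0|0	0|0	0|0	0|1	0|0	0|0	0|0	1|1	0|1	0|1	0|1
19	200000	v19_200000	A	G	.	PASS	AF=0.39528	GT	0|1	0|0	0|0	0|1	1|0	1|0	1|1	1|1	0|1	0|1	0|1	0|0	0|1	1|0	1|0	1|0	0|0	0|0	1|1	1|0	0|1	0|1	0|0	0|1	0|0	1|0	0|1	0|0	1|0	1|1
20	100000	v20_100000	A	G	.	PASS	AF=0.231786	GT	0|0	1|0	0|0	0|1	0|1	0|1	0|0	0|1	0|1	0|1	0|1	0|1	0|0	0|1	1|0	1|0	1|0	1|0	0|0	1|0	0|0	0|0	0|0	0|1	0|0	1|0	1|0	0|0	0|1	0|0
20	200000	v20_200000	A	G	.	PASS	AF=0.768703	GT	1|0	1|0	0|1	0|1	1|0	1|0	0|1	0|1	1|0	1|1	0|0	0|0	1|1	1|1	0|1	1|1	0|0	0|0	0|0	0|1	1|0	1|0	0|1	1|1	0|1	0|1	1|1	1|1	1|1	1|1
21	100000	v21_100000	A	G	.	PASS	AF=0.272091	GT	0|0	1|0	0|1	0|1	0|0	0|0	1|0	1|0	0|0	0|0	1|0	1|0	0|1	1|0	0|0	0|0	0|0	1|0	0|0	0|1	0|0	0|1	0|0	0|0	0|0	0|0	1|1	0|1	0|1	0|1
21	200000	v21_200000	A	G	.	PASS	AF=0.527234	GT	1|0	1|0	1|1	1|1	0|1	0|1	1|0	0|1	1|1	1|1	0|0	0|0	1|0	1|1	1|0	0|1	0|1	1|1	1|1	1|1	0|0	0|0	0|1	0|0	1|1	1|1	1|1	0|0	0|1	0|1
22	100000	v22_100000	A	G	.	PASS	AF=0.486526	GT	1|1	1|0	1|0	1|0	0|0	1|1	1|0	1|0	1|0	1|0	0|1	0|1	0|0	0|0	0|1	0|0	1|0	1|1	1|1	1|1	0|1	0|1	0|1	1|1	1|1	0|1	0|0	0|0	0|0	1|0
22	200000	v22_200000	A	G	.	PASS	AF=0.263684	GT	0|1	0|1	0|0	0|0	0|0	0|0	0|0	1|0	0|1	1|0	0|0	0|0	1|1	1|1	0|0	0|0	0|1	0|1	1|0	1|0	0|1	0|0	0|0	0|1	0|1	0|1	1|0	1|0	0|1	0|1
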