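iid	y	sex
I00001	-7.4339	M
I00002	-2.1294	F
I00003	-3.3469	M
I00004	-13.8861	F
I00005	-10.4371	M
I00006	-3.02	F
I00007	-8.7656	M
I00008	-3.0275	F
I00009	-7.5361	M
I00010	-7.5204	F
I00011	-13.5797	M
I00012	-2.4317	F
I00013	7.6571	M
I00014	7.0323	F
I00015	-7.3685	M
I00016	0.4755	F
I00017	-1.2119	M
I00018	-1.8673	F
I00019	-8.0029	M
I00020	-4.8336	F
I00021	2.4227	M
I00022	3.0455	F
I00023	0.0015	M
I00024	11.0485	F
I00025	2.1127	M
I00026	11.5758	F
I00027	0.2379	M
I00028	11.307	F
I00029	9.3043	M
I00030	15.1959	F
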