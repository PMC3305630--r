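target	block	cds_start	stop	length_aa
SPOA_PG001	novel	300016	300507	164
SPO_PG002	novel	3171305	3170874	144
SPO_PG003	novel	1412876	1413418	181
SPOA_PG004	novel	87032	87709	226
SPO_PG005	novel	358784	358125	220
SPO_PG006	novel	360911	360405	169
SPO_PG007	novel	1483195	1482533	221
SPO_PG008	novel	1431167	1431595	143
SPO_PG009	novel	501740	502171	144
SPO_PG010	novel	2353576	2353965	130
SPO_PG011	novel	1374589	1374299	97
SPO_PG012	novel	3703461	3702955	169
SPO_PG013	novel	649156	649749	198
SPO_PG014	novel	2482691	2482317	125
SPO_PG015	novel	3657397	3656924	158
SPO_PG016	novel	373055	373333	93
SPO_PG017	novel	1092236	1092592	119
SPO_PG018	novel	495167	495529	121
SPO_PG019	novel	1418666	1419187	174
SPO_PG020	novel	2807747	2807223	175
SPO_PG021	novel	1289473	1289829	119
SPO_PG022	novel	1151078	1151632	185
SPO_PG023	novel	1400166	1399696	157
SPO_PG024	novel	2628409	2629668	420
SPO_PG025	novel	1322016	1322357	114
SPO_PG026	novel	3883013	3882531	161
SPO_PG027	wrong_cds	501090	501710	207
SPO_PG028	wrong_cds	2429044	2427941	368
SPO_PG029	wrong_cds	3124885	3123728	386
SPO_PG030	wrong_cds	1738173	1736680	498
SPO_PG031	wrong_cds	2905673	2906335	221
SPO_PG032	wrong_cds	3751605	3751147	153
SPO_PG033	wrong_cds	2357076	2357507	144
SPO_PG034	wrong_cds	934724	935068	115
SPO_PG035	wrong_cds	2751483	2750281	401
SPO_PG036	seq_error	562052	560282	590
SPO_PG037	seq_error	3188876	3188459	139
SPO_PG038	seq_error	2152217	2151179	346
SPO_PG039	seq_error	3515528	3515111	139
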