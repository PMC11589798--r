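sex	age	L	M	S	height_m
male	2	-2.2	16.5	0.08	0.87
male	2.5	-2.2	16.3196	0.08377	0.9077
male	3	-2.2	16.1414	0.08753	0.9456
male	3.5	-2.2	15.9675	0.09128	0.9832
male	4	-2.2	15.8	0.095	1.02
male	4.5	-2.2	15.6436	0.0987	1.0562
male	5	-2.2	15.5132	0.10241	1.0919
male	5.5	-2.2	15.4262	0.10617	1.1266
male	6	-2.2	15.4	0.11	1.16
male	6.5	-2.2	15.4465	0.11392	1.1916
male	7	-2.2	15.5557	0.11782	1.2219
male	7.5	-2.2	15.712	0.12156	1.2512
male	8	-2.2	15.9	0.125	1.28
male	8.5	-2.2	16.1064	0.12804	1.3084
male	9	-2.2	16.3266	0.1307	1.3362
male	9.5	-2.2	16.5586	0.133	1.3634
male	10	-2.2	16.8	0.135	1.39
male	10.5	-2.2	17.0499	0.13672	1.4145
male	11	-2.2	17.3128	0.13815	1.4375
male	11.5	-2.2	17.5942	0.13925	1.4617
male	12	-2.2	17.9	0.14	1.49
male	12.5	-2.2	18.233	0.14038	1.5254
male	13	-2.2	18.5847	0.14045	1.5656
male	13.5	-2.2	18.9441	0.1403	1.6055
male	14	-2.2	19.3	0.14	1.64
male	14.5	-2.2	19.6432	0.13962	1.6681
male	15	-2.2	19.9733	0.13917	1.6925
male	15.5	-2.2	20.2917	0.13863	1.7131
male	16	-2.2	20.6	0.138	1.73
male	16.5	-2.2	20.8987	0.13727	1.7422
male	17	-2.2	21.1846	0.13649	1.75
male	17.5	-2.2	21.4531	0.13571	1.7553
male	18	-2.2	21.7	0.135	1.76
male	18.5	-2.2	21.9227	0.13439	1.7639
male	19	-2.2	22.126	0.13388	1.7663
male	19.5	-2.2	22.3162	0.13342	1.768
male	20	-2.2	22.5	0.133	1.77
female	2	-2	16.4	0.085	0.86
female	2.5	-2	16.1531	0.08877	0.8977
female	3	-2	15.915	0.09253	0.9356
female	3.5	-2	15.6943	0.09627	0.9732
female	4	-2	15.5	0.1	1.01
female	4.5	-2	15.3413	0.1037	1.0462
female	5	-2	15.2301	0.10741	1.0819
female	5.5	-2	15.1789	0.11117	1.1166
female	6	-2	15.2	0.115	1.15
female	6.5	-2	15.3003	0.11892	1.1816
female	7	-2	15.4645	0.12281	1.2119
female	7.5	-2	15.6714	0.12655	1.2412
female	8	-2	15.9	0.13	1.27
female	8.5	-2	16.1338	0.13305	1.2977
female	9	-2	16.3744	0.1357	1.3244
female	9.5	-2	16.6278	0.13801	1.3513
female	10	-2	16.9	0.14	1.38
female	10.5	-2	17.1955	0.1417	1.412
female	11	-2	17.5128	0.14312	1.4463
female	11.5	-2	17.8486	0.14422	1.4798
female	12	-2	18.2	0.145	1.51
female	12.5	-2	18.5622	0.14545	1.537
female	13	-2	18.9244	0.14558	1.5619
female	13.5	-2	19.2745	0.14542	1.5834
female	14	-2	19.6	0.145	1.6
female	14.5	-2	19.8917	0.14436	1.6102
female	15	-2	20.152	0.14357	1.615
female	15.5	-2	20.3863	0.14276	1.6173
female	16	-2	20.6	0.142	1.62
female	16.5	-2	20.7976	0.14138	1.6237
female	17	-2	20.9801	0.14088	1.6269
female	17.5	-2	21.1476	0.14043	1.6291
female	18	-2	21.3	0.14	1.63
female	18.5	-2	21.4381	0.13954	1.63
female	19	-2	21.565	0.13904	1.63
female	19.5	-2	21.6843	0.13853	1.63
female	20	-2	21.8	0.138	1.63
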