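sample_id	chrom	start	end	cnv_type	n_probes	dataset_id
S00001	1	1000000	1300000	DUP	60	ds_GSA
S00001	1	1420347	1578855	DEL	32	ds_GSA
S00001	2	419270	714489	DEL	59	ds_GSA
S00002	1	1000000	1300000	DUP	60	ds_GSA
S00002	2	521838	571864	DEL	10	ds_GSA
S00002	3	1357742	1394530	DUP	7	ds_GSA
S00004	2	2781316	3000370	DUP	44	ds_GSA
S00005	1	261572	404062	DEL	28	ds_GSA
S00007	1	1000000	1300000	DUP	60	ds_GSA
S00008	1	1000000	1300000	DUP	60	ds_GSA
S00009	1	4106232	4226881	DEL	24	ds_GSA
S00009	3	1138343	1238920	DEL	20	ds_GSA
S00011	1	1952092	2045843	DEL	19	ds_GSA
S00012	3	1307793	1442150	DEL	27	ds_GSA
S00012	3	2799550	2877707	DUP	16	ds_GSA
S00014	1	3850426	3887858	DUP	7	ds_GSA
S00015	3	1368835	1497462	DUP	26	ds_GSA
S00017	3	2646730	2958520	DEL	62	ds_GSA
S00018	1	879446	1029720	DEL	30	ds_GSA
S00018	1	1313040	1871267	DEL	112	ds_GSA
S00018	2	2980698	3122462	DUP	28	ds_GSA
S00019	1	4097328	4391664	DUP	59	ds_GSA
S00020	1	4470178	4580810	DEL	22	ds_GSA
S00020	2	1203401	1359133	DEL	31	ds_GSA
S00020	3	2704645	2749102	DEL	9	ds_GSA
S00021	1	3987481	4049414	DUP	12	ds_GSA
S00021	2	2665815	2719809	DUP	11	ds_GSA
S00021	3	988173	1187521	DEL	40	ds_GSA
S00022	2	991561	1304046	DEL	62	ds_GSA
S00026	1	4732674	4791122	DEL	12	ds_GSA
S00026	2	469613	600605	DUP	26	ds_GSA
S00029	2	1243531	1393286	DUP	30	ds_GSA
S00031	1	3050456	3199115	DUP	30	ds_GSA
S00031	3	685426	852260	DUP	33	ds_GSA
S00032	2	2289804	2427120	DUP	27	ds_GSA
S00032	2	3503175	3731231	DUP	46	ds_GSA
S00034	1	1000000	1300000	DUP	60	ds_GSA
S00034	1	1759090	1885138	DUP	25	ds_GSA
S00034	1	2939699	3107514	DEL	34	ds_GSA
S00035	1	2948885	3059614	DEL	22	ds_GSA
S00036	1	1000000	1300000	DUP	60	ds_GSA
S00036	3	2255348	2695370	DUP	88	ds_GSA
S00038	1	3132081	3164915	DUP	7	ds_GSA
S00039	1	2729230	2930825	DUP	40	ds_GSA
S00039	1	4062824	4370651	DEL	62	ds_GSA
S00039	3	2651259	2777311	DUP	25	ds_GSA
S00040	1	1000000	1300000	DUP	60	ds_GSA
S00040	3	2016261	2315725	DEL	60	ds_GSA
S00041	1	694076	788545	DEL	19	ds_GSA
S00041	1	1854291	2123512	DUP	54	ds_GSA
S00042	1	1000000	1300000	DUP	60	ds_GSA
S00042	1	1202960	1251121	DEL	10	ds_GSA
S00042	1	4301887	4750197	DEL	90	ds_GSA
S00043	1	105119	379732	DUP	55	ds_GSA
S00044	1	1000000	1300000	DUP	60	ds_GSA
S00044	1	1173071	1212263	DUP	8	ds_GSA
S00044	2	887293	992141	DUP	21	ds_GSA
S00045	3	1140740	1852051	DUP	142	ds_GSA
S00045	3	1646270	1686902	DEL	8	ds_GSA
S00045	3	1870099	2048184	DUP	36	ds_GSA
S00046	1	1000000	1300000	DUP	60	ds_GSA
S00049	1	556874	738509	DUP	36	ds_GSA
S00049	1	3004674	3335696	DUP	66	ds_GSA
S00050	1	1253166	1348026	DUP	19	ds_GSA
S00050	1	2966543	3236349	DEL	54	ds_GSA
S00052	2	874064	1166547	DUP	58	ds_GSA
S00053	3	992135	1184175	DUP	38	ds_GSA
S00054	2	1175567	1348907	DUP	35	ds_GSA
S00055	2	2850049	3152347	DEL	60	ds_GSA
S00056	1	1084191	1337308	DEL	51	ds_GSA
S00056	3	1336452	1433193	DEL	19	ds_GSA
S00057	1	4024365	4222172	DEL	40	ds_GSA
S00059	1	1261711	1342039	DUP	16	ds_GSA
S00060	2	1734104	1967377	DUP	47	ds_GSA
S00063	2	3244628	3355430	DUP	22	ds_GSA
S00065	1	1583363	1789210	DEL	41	ds_GSA
S00066	2	1923454	2117527	DEL	39	ds_GSA
S00066	3	501742	709525	DUP	42	ds_GSA
S00066	3	2219211	2343345	DUP	25	ds_GSA
S00069	1	4741155	4965388	DEL	45	ds_GSA
S00071	3	2746956	2874587	DUP	26	ds_OmniExpress
S00073	1	558649	956281	DEL	80	ds_OmniExpress
S00073	1	2410146	2750915	DEL	68	ds_OmniExpress
S00073	2	2199087	2293459	DEL	19	ds_OmniExpress
S00074	1	184006	271055	DEL	17	ds_OmniExpress
S00074	3	2657208	2872095	DEL	43	ds_OmniExpress
S00075	2	47541	126689	DEL	16	ds_OmniExpress
S00075	2	2243386	2352898	DEL	22	ds_OmniExpress
S00076	1	924393	1024797	DEL	20	ds_OmniExpress
S00076	1	1000000	1300000	DUP	60	ds_OmniExpress
S00076	1	3517200	3780341	DUP	53	ds_OmniExpress
S00077	1	1473817	1512715	DEL	8	ds_OmniExpress
S00077	1	1938092	1986947	DEL	10	ds_OmniExpress
S00077	1	3058609	3076748	DUP	4	ds_OmniExpress
S00077	1	3247033	3305147	DEL	12	ds_OmniExpress
S00077	3	1234210	1473030	DUP	48	ds_OmniExpress
S00078	2	2719614	2988020	DEL	54	ds_OmniExpress
S00081	1	691089	898404	DUP	41	ds_OmniExpress
S00081	3	904002	1082826	DEL	36	ds_OmniExpress
S00082	1	254947	525912	DUP	54	ds_OmniExpress
S00082	1	1000000	1300000	DUP	60	ds_OmniExpress
S00082	1	4398874	4621452	DEL	45	ds_OmniExpress
S00082	2	100632	169813	DEL	14	ds_OmniExpress
S00082	2	3681266	3826923	DUP	29	ds_OmniExpress
S00083	1	2790921	2888997	DUP	20	ds_OmniExpress
S00083	2	1101324	1223573	DEL	24	ds_OmniExpress
S00083	2	1329699	1703226	DUP	75	ds_OmniExpress
S00083	3	2058523	2111006	DUP	10	ds_OmniExpress
S00085	3	33418	94234	DEL	12	ds_OmniExpress
S00086	1	2004113	2247952	DEL	49	ds_OmniExpress
S00086	1	3010885	3109498	DUP	20	ds_OmniExpress
S00090	1	22057	383632	DUP	72	ds_OmniExpress
S00091	1	3214657	3370382	DUP	31	ds_OmniExpress
S00092	1	4107806	4555184	DEL	89	ds_OmniExpress
S00092	2	385749	566401	DUP	36	ds_OmniExpress
S00092	3	318079	567789	DUP	50	ds_OmniExpress
S00093	1	1213449	1387287	DUP	35	ds_OmniExpress
S00093	2	2081446	2400176	DUP	64	ds_OmniExpress
S00094	2	2728767	2976743	DUP	50	ds_OmniExpress
S00094	2	3664957	3817328	DUP	30	ds_OmniExpress
S00094	3	1713328	1765391	DUP	10	ds_OmniExpress
S00095	1	1937379	2148674	DEL	42	ds_OmniExpress
S00095	3	1411702	1544511	DEL	27	ds_OmniExpress
S00096	1	1000000	1300000	DUP	60	ds_OmniExpress
S00100	1	3317712	3381671	DEL	13	ds_OmniExpress
S00100	3	1294273	1530104	DUP	47	ds_OmniExpress
S00101	2	1159612	1238586	DEL	16	ds_OmniExpress
S00102	1	2696729	2759179	DEL	12	ds_OmniExpress
S00105	2	2772895	3000380	DEL	45	ds_OmniExpress
S00105	2	3037624	3100910	DUP	13	ds_OmniExpress
S00106	1	3927017	4105000	DEL	36	ds_OmniExpress
S00108	1	1000000	1300000	DUP	60	ds_OmniExpress
S00108	3	949319	1099610	DUP	30	ds_OmniExpress
S00109	2	3512218	3571416	DEL	12	ds_OmniExpress
S00111	1	1000000	1300000	DUP	60	ds_OmniExpress
S00112	1	1437770	1780322	DEL	69	ds_OmniExpress
S00114	2	706676	1054126	DEL	69	ds_OmniExpress
S00114	2	2725858	2824913	DEL	20	ds_OmniExpress
S00115	1	4778476	4886043	DEL	22	ds_OmniExpress
S00116	2	659411	759704	DUP	20	ds_OmniExpress
S00117	2	656695	803452	DEL	29	ds_OmniExpress
S00118	1	1000000	1300000	DUP	60	ds_OmniExpress
S00118	1	3585176	3702040	DEL	23	ds_OmniExpress
S00118	3	1810944	1927689	DEL	23	ds_OmniExpress
S00119	1	1000000	1300000	DUP	60	ds_OmniExpress
S00119	3	2741132	2822280	DEL	16	ds_OmniExpress
S00120	3	2255583	2319758	DUP	13	ds_OmniExpress
S00121	2	626908	857335	DUP	46	ds_OmniExpress
S00122	1	1377563	1462873	DUP	17	ds_OmniExpress
S00124	2	3261154	3366278	DEL	21	ds_OmniExpress
S00124	3	1251458	1308690	DEL	11	ds_OmniExpress
S00126	1	744551	830176	DEL	17	ds_OmniExpress
S00126	1	3307748	3340068	DEL	6	ds_OmniExpress
S00129	3	1907267	2075889	DEL	34	ds_OmniExpress
S00129	3	2354149	2476510	DUP	24	ds_OmniExpress
S00131	1	1808159	1992524	DUP	37	ds_OmniExpress
S00132	3	2478383	2675847	DEL	39	ds_OmniExpress
S00133	2	2241620	2316064	DEL	15	ds_OmniExpress
S00134	3	1353723	1473141	DEL	24	ds_OmniExpress
S00138	2	2497256	2571310	DUP	15	ds_OmniExpress
S00139	1	3631786	3727929	DEL	19	ds_OmniExpress
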