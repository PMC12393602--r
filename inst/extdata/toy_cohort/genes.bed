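1	27203	31426	G0001
1	37760	41983	G0001
1	48317	52540	G0001
1	79276	82245	G0002
1	86699	89668	G0002
1	94121	97090	G0002
1	101544	104513	G0002
1	116674	128223	G0003
1	160023	161536	G0004
1	163806	165319	G0004
1	167590	169103	G0004
1	205815	208279	G0005
1	211976	214440	G0005
1	218136	220600	G0005
1	224297	226761	G0005
1	260813	271633	G0006
1	319243	322411	G0007
1	327164	330332	G0007
1	369275	382390	G0008
1	417331	422167	G0009
1	429421	434257	G0009
1	441511	446347	G0009
1	486830	493379	G0010
1	527539	529385	G0011
1	532155	534001	G0011
1	553952	557046	G0012
1	561686	564780	G0012
1	569421	572515	G0012
1	577155	580249	G0012
1	590917	598540	G0013
1	609974	617597	G0013
1	665534	667329	G0014
1	670023	671818	G0014
1	702842	708286	G0015
1	716451	721895	G0015
1	756886	762528	G0016
1	793675	796407	G0017
1	800505	803237	G0017
1	837316	840781	G0018
1	872105	873776	G0019
1	876282	877953	G0019
1	899421	901233	G0020
1	903951	905763	G0020
1	908481	910293	G0020
1	934152	935945	G0021
1	938635	940428	G0021
1	943118	944911	G0021
1	947601	949394	G0021
1	977494	979158	G0022
1	981654	983318	G0022
1	985814	987478	G0022
1	989974	991638	G0022
1	1029347	1032441	G0023
1	1037082	1040176	G0023
1	1044816	1047910	G0023
1	1066057	1070554	G0024
1	1077299	1081796	G0024
1	1088542	1093039	G0024
1	1119526	1120715	G0025
1	1122499	1123688	G0025
1	1125472	1126661	G0025
1	1128445	1129634	G0025
1	1168645	1169712	G0026
1	1171312	1172379	G0026
1	1173980	1175047	G0026
1	1176647	1177714	G0026
1	1192108	1197795	G0027
1	1206326	1212013	G0027
1	1235228	1248640	G0028
1	1288412	1302856	G0029
1	1346009	1351104	G0030
1	1358747	1363842	G0030
1	1406068	1412443	G0031
1	1422006	1428381	G0031
1	1460260	1463322	G0032
1	1467915	1470977	G0032
1	1500502	1505318	G0033
1	1512542	1517358	G0033
1	1524583	1529399	G0033
1	1570009	1573050	G0034
1	1577610	1580651	G0034
1	1585212	1588253	G0034
1	1592813	1595854	G0034
1	1627225	1628660	G0035
1	1630812	1632247	G0035
1	1634399	1635834	G0035
1	1666918	1669157	G0036
1	1672514	1674753	G0036
1	1678111	1680350	G0036
1	1683707	1685946	G0036
1	1720854	1721924	G0037
1	1723529	1724599	G0037
1	1726203	1727273	G0037
1	1728878	1729948	G0037
1	1741158	1753104	G0038
1	1788780	1790245	G0039
1	1792443	1793908	G0039
1	1796106	1797571	G0039
1	1799769	1801234	G0039
1	1841775	1845660	G0040
1	1851488	1855373	G0040
1	1868232	1870749	G0041
1	1874525	1877042	G0041
1	1897088	1897910	G0042
1	1899142	1899964	G0042
1	1901197	1902019	G0042
1	1903251	1904073	G0042
1	1911485	1915893	G0043
1	1922506	1926914	G0043
1	1961325	1966710	G0044
1	1974787	1980172	G0044
1	1997746	2003223	G0045
1	2011438	2016915	G0045
1	2054463	2057575	G0046
1	2062242	2065354	G0046
1	2070021	2073133	G0046
1	2106256	2110003	G0047
1	2115625	2119372	G0047
1	2124993	2128740	G0047
1	2134362	2138109	G0047
1	2176928	2181442	G0048
1	2209090	2221427	G0049
1	2246031	2251866	G0050
1	2260619	2266454	G0050
1	2293483	2295348	G0051
1	2298146	2300011	G0051
1	2302809	2304674	G0051
1	2307472	2309337	G0051
1	2349245	2350618	G0052
1	2352677	2354050	G0052
1	2356110	2357483	G0052
1	2359542	2360915	G0052
1	2377933	2384352	G0053
1	2425757	2429437	G0054
1	2434957	2438637	G0054
1	2444156	2447836	G0054
1	2453356	2457036	G0054
1	2490839	2495098	G0055
1	2501485	2505744	G0055
1	2512132	2516391	G0055
1	2533187	2535647	G0056
1	2539337	2541797	G0056
1	2545488	2547948	G0056
1	2551638	2554098	G0056
1	2582718	2591765	G0057
1	2628152	2629583	G0058
1	2631728	2633159	G0058
1	2635305	2636736	G0058
1	2662744	2664657	G0059
1	2667527	2669440	G0059
1	2672311	2674224	G0059
1	2683791	2687923	G0060
1	2694120	2698252	G0060
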